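#' Weighted undirected network
#'
#' The basic container for interaction / similarity networks: a set of node
#' identifiers plus undirected weighted edges.  Self-loops are dropped on
#' construction and duplicate unordered pairs are collapsed keeping the
#' maximum weight (conservative for similarity semantics); both events are
#' reported via a message.  Edge endpoints are always stored with
#' `source < target` lexicographically and the node set is kept sorted, so a
#' network is a deterministic function of its content, independent of input
#' order.
#'
#' @param edges data.frame with columns `source`, `target` and optionally
#'   `weight` (defaults to 1); extra columns are preserved.
#' @param nodes optional character vector of node ids in addition to edge
#'   endpoints (isolated nodes).
#' @param node_attributes optional data.frame of per-node attributes with a
#'   `node` column.
#' @return An object of class `weighted_network` with elements `nodes`,
#'   `edges`, `node_attributes`.
#' @examples
#' net <- weighted_network(data.frame(source = c("a", "b"), target = c("b", "a"),
#'                                    weight = c(2, 3)))
#' n_edges(net)  # 1 edge, weight 3
#' @export
weighted_network <- function(edges = NULL, nodes = NULL, node_attributes = NULL) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("source", "target") %in% names(edges))) {
      stop_data("edge table must have 'source' and 'target' columns")
    }
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    if (is.null(edges$weight)) edges$weight <- 1.0
    edges$weight <- as.numeric(edges$weight)
    if (anyNA(edges$weight)) stop_data("edge weights must be numeric and non-missing")

    loops <- edges$source == edges$target
    if (any(loops)) {
      ck_message("dropped ", sum(loops), " self-loop(s)")
      edges <- edges[!loops, , drop = FALSE]
    }
    # store unordered pairs canonically
    swap <- edges$source > edges$target
    if (any(swap)) {
      tmp <- edges$source[swap]
      edges$source[swap] <- edges$target[swap]
      edges$target[swap] <- tmp
    }
    key <- paste(edges$source, edges$target, sep = "\r")
    if (anyDuplicated(key)) {
      n_before <- nrow(edges)
      keep <- unlist(lapply(split(seq_along(key), key), function(idx) {
        idx[which.max(edges$weight[idx])]
      }), use.names = FALSE)
      edges <- edges[lex_sort_idx_keep(keep), , drop = FALSE]
      ck_message("collapsed ", n_before - nrow(edges),
                 " duplicate edge(s), keeping the maximum weight")
      key <- paste(edges$source, edges$target, sep = "\r")
    }
    edges <- edges[lex_order(edges$source, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- lex_sort(unique(c(as.character(nodes %||% character()),
                             edges$source, edges$target)))
  structure(list(nodes = nodes, edges = edges, node_attributes = node_attributes),
            class = "weighted_network")
}

# keep original ordering of a subset of row indices
lex_sort_idx_keep <- function(idx) idx[order(idx)]

#' @export
print.weighted_network <- function(x, ...) {
  cat("weighted_network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$edges) > 0L) {
    w <- x$edges$weight
    cat("  weight range: [", format(min(w)), ", ", format(max(w)), "]\n", sep = "")
  }
  invisible(x)
}

#' Network size accessors
#' @param network a `weighted_network`
#' @return integer count
#' @export
n_nodes <- function(network) length(network$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(network) nrow(network$edges)

# Convert to an igraph graph (vertex order = network$nodes).
as_igraph <- function(network, weighted = TRUE) {
  ed <- network$edges
  d <- if (weighted) ed[, c("source", "target", "weight")] else ed[, c("source", "target")]
  igraph::graph_from_data_frame(d, directed = FALSE,
                                vertices = data.frame(name = network$nodes))
}

# Named adjacency list (character neighbors), sorted lexicographically.
adjacency_list <- function(network) {
  adj <- stats::setNames(vector("list", length(network$nodes)), network$nodes)
  for (i in seq_along(adj)) adj[[i]] <- character()
  ed <- network$edges
  for (i in seq_len(nrow(ed))) {
    s <- ed$source[i]; t <- ed$target[i]
    adj[[s]] <- c(adj[[s]], t)
    adj[[t]] <- c(adj[[t]], s)
  }
  lapply(adj, lex_sort)
}
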