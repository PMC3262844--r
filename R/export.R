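#' Cluster network: drop or label inter-cluster edges
#'
#' Builds the network view of a clustering result: with
#' `restore_inter_cluster = FALSE` only edges whose endpoints share a
#' cluster survive; with `TRUE` all input edges are kept and labeled
#' `intra` / `inter` in an `edge_type` column.  Never invents edges.
#'
#' @param network a `weighted_network`
#' @param assignment a `cluster_assignment` covering every network node
#' @param restore_inter_cluster keep inter-cluster edges, labeled
#' @return a `weighted_network` whose edge table has an `edge_type` column
#' @export
build_cluster_network <- function(network, assignment, restore_inter_cluster = FALSE) {
  covered <- c(unlist(assignment$clusters, use.names = FALSE), assignment$unassigned)
  missing <- setdiff(network$nodes, covered)
  if (length(missing) > 0L) {
    stop_data("assignment does not cover node(s): ", paste(missing, collapse = ", "))
  }
  ed <- network$edges
  lab <- assignment$labels
  ls <- lab[ed$source]; lt <- lab[ed$target]
  intra <- !is.na(ls) & !is.na(lt) & ls == lt
  ed$edge_type <- ifelse(intra, "intra", "inter")
  if (!restore_inter_cluster) ed <- ed[intra, , drop = FALSE]
  rownames(ed) <- NULL
  out <- network
  out$edges <- ed
  out
}

#' Nested group tree from a dendrogram
#'
#' One group per internal merge, each containing its two children (child
#' groups or leaf ids); the root group holds all leaves.  Group ids are
#' stable, derived from the smallest member id and the group size (unique
#' within a tree since sizes strictly grow along any path).
#'
#' @param tree an `hclust` object
#' @return list of groups in merge order; each has `id`, `children`
#'   (leaf ids or group ids) and `members` (all leaf ids)
#' @export
hierarchy_groups <- function(tree) {
  n <- length(tree$labels)
  groups <- vector("list", n - 1L)
  members <- vector("list", n - 1L)
  gid <- character(n - 1L)
  for (s in seq_len(n - 1L)) {
    ch <- tree$merge[s, ]
    child_ids <- character(2)
    mem <- character(0)
    for (t in 1:2) {
      if (ch[t] < 0) {
        child_ids[t] <- tree$labels[-ch[t]]
        mem <- c(mem, tree$labels[-ch[t]])
      } else {
        child_ids[t] <- gid[ch[t]]
        mem <- c(mem, members[[ch[t]]])
      }
    }
    mem <- lex_sort(mem)
    members[[s]] <- mem
    gid[s] <- sprintf("GRP_%s_%d", mem[1], length(mem))
    groups[[s]] <- list(id = gid[s], children = child_ids, members = mem)
  }
  groups
}

#' Ensemble co-clustering (fuzzy) network
#'
#' Runs a clustering function over an ensemble of seeds and connects node
#' pairs by the frequency with which they co-cluster; the fuzzy-network
#' view of how clusters and their members relate.  The consensus partition
#' is the connected components of pairs co-clustering in more than half of
#' the runs.  Output is limited to the `max_edges` highest-frequency pairs
#' (ties by lexicographic pair), the usual cap on fuzzy-network display.
#'
#' @param input the clustering input (network, matrix, ...) forwarded to
#'   `algorithm`
#' @param algorithm function `(input, seed, ...) -> cluster_assignment`
#' @param n_runs ensemble size (runs use seeds `seed .. seed + n_runs - 1`)
#' @param seed base seed
#' @param max_edges cap on reported pairs (default all)
#' @param ... forwarded to `algorithm`
#' @return object of class `cocluster_network`: `pairs` (data.frame node1,
#'   node2, frequency), `n_runs`, `consensus` (a `cluster_assignment`)
#' @export
ensemble_cocluster <- function(input, algorithm, n_runs, seed = 42,
                               max_edges = Inf, ...) {
  if (!is_count(n_runs)) stop_config("n_runs must be a positive integer")
  counts <- new.env(parent = emptyenv())
  all_nodes <- character(0)
  for (r in seq_len(n_runs)) {
    res <- algorithm(input, seed = seed + r - 1L, ...)
    all_nodes <- unique(c(all_nodes, unlist(res$clusters, use.names = FALSE),
                          res$unassigned))
    for (cl in res$clusters) {
      if (length(cl) < 2L) next
      for (i in seq_len(length(cl) - 1L)) {
        for (j in (i + 1L):length(cl)) {
          key <- paste(cl[i], cl[j], sep = "\t")
          counts[[key]] <- (counts[[key]] %||% 0L) + 1L
        }
      }
    }
  }
  keys <- ls(counts)
  if (length(keys) > 0L) {
    freq <- vapply(keys, function(k) counts[[k]], numeric(1)) / n_runs
    parts <- strsplit(keys, "\t", fixed = TRUE)
    pairs <- data.frame(node1 = vapply(parts, `[`, character(1), 1L),
                        node2 = vapply(parts, `[`, character(1), 2L),
                        frequency = unname(freq), stringsAsFactors = FALSE)
    pairs <- pairs[lex_order(-pairs$frequency, pairs$node1, pairs$node2), , drop = FALSE]
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(node1 = character(), node2 = character(),
                        frequency = numeric(), stringsAsFactors = FALSE)
  }
  if (n_runs > 1L && nrow(pairs) > 0L && all(pairs$frequency %in% c(0, 1))) {
    ck_message("all co-clustering frequencies are 0 or 1: the ensemble was unanimous ",
               "(deterministic algorithm?)")
  }

  consensus_pairs <- pairs[pairs$frequency > 0.5, , drop = FALSE]
  g <- igraph::graph_from_data_frame(consensus_pairs[, c("node1", "node2")],
                                     directed = FALSE,
                                     vertices = data.frame(name = lex_sort(all_nodes)))
  comp <- igraph::components(g)
  consensus <- assignment_from_labels(stats::setNames(comp$membership,
                                                      igraph::V(g)$name))
  if (is.finite(max_edges) && nrow(pairs) > max_edges) {
    pairs <- pairs[seq_len(max_edges), , drop = FALSE]
  }
  structure(list(pairs = pairs, n_runs = n_runs, consensus = consensus),
            class = "cocluster_network")
}

#' @export
print.cocluster_network <- function(x, ...) {
  cat("cocluster_network:", nrow(x$pairs), "pairs over", x$n_runs, "runs;",
      n_clusters(x$consensus), "consensus clusters\n")
  invisible(x)
}

#' Write a co-clustering network as TSV
#'
#' Columns: node1, node2, frequency, consensus_cluster (the shared
#' consensus cluster index, empty when the pair straddles two).
#' @param cocluster a `cocluster_network`
#' @param path output path
#' @export
write_cocluster <- function(cocluster, path) {
  lab <- cocluster$consensus$labels
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("node1\tnode2\tfrequency\tconsensus_cluster", con, sep = "\n")
  p <- cocluster$pairs
  for (i in seq_len(nrow(p))) {
    l1 <- lab[p$node1[i]]; l2 <- lab[p$node2[i]]
    cc <- if (!is.na(l1) && !is.na(l2) && l1 == l2) as.character(l1) else ""
    writeLines(sprintf("%s\t%s\t%.17g\t%s", p$node1[i], p$node2[i], p$frequency[i], cc),
               con, sep = "\n")
  }
  invisible(path)
}

#' Heat-map table with cluster separators
#'
#' Orders matrix rows by cluster (size order; input row order preserved
#' within each cluster), emits the separator indices drawn between clusters,
#' and maps values to colors on a symmetric diverging scale anchored at 0
#' (`yellow_cyan` is the EMAP convention: cyan negative, black zero, yellow
#' positive).
#'
#' @param matrix an `attribute_matrix` or numeric matrix
#' @param assignment a `cluster_assignment` covering the matrix rows
#' @param color_scale `"yellow_cyan"`, `"red_green"`, or a character vector
#'   of 3 color anchors (low, mid, high)
#' @return list with `table` (reordered matrix), `row_clusters`,
#'   `separators` (row indices after which a bar is drawn), `colors`
#'   (matrix of hex colors, `NA` cells for missing values) and `limit`
#' @export
heatmap_table <- function(matrix, assignment, color_scale = "yellow_cyan") {
  v <- if (inherits(matrix, "attribute_matrix")) matrix$values else as.matrix(matrix)
  covered <- c(unlist(assignment$clusters, use.names = FALSE), assignment$unassigned)
  if (!all(rownames(v) %in% covered)) {
    stop_data("assignment does not cover all matrix rows")
  }
  anchors <- if (length(color_scale) == 3L) color_scale
             else switch(color_scale,
                         yellow_cyan = c("#00FFFF", "#000000", "#FFFF00"),
                         red_green   = c("#00FF00", "#000000", "#FF0000"),
                         stop_config("unknown color scale: ", color_scale))
  order_rows <- character(0)
  row_clusters <- integer(0)
  for (ci in seq_along(assignment$clusters)) {
    members <- intersect(rownames(v), assignment$clusters[[ci]])  # input order
    order_rows <- c(order_rows, members)
    row_clusters <- c(row_clusters, rep(ci, length(members)))
  }
  leftover <- setdiff(rownames(v), order_rows)
  order_rows <- c(order_rows, leftover)
  row_clusters <- c(row_clusters, rep(NA_integer_, length(leftover)))
  tab <- v[order_rows, , drop = FALSE]
  sizes <- table(factor(row_clusters, levels = unique(row_clusters[!is.na(row_clusters)])))
  separators <- cumsum(sizes)
  separators <- separators[-length(separators)]

  limit <- max(abs(tab), na.rm = TRUE)
  if (!is.finite(limit) || limit == 0) limit <- 1
  ramp <- grDevices::colorRamp(anchors)
  colors <- matrix(NA_character_, nrow(tab), ncol(tab), dimnames = dimnames(tab))
  ok <- !is.na(tab)
  scaled <- (pmin(pmax(tab[ok], -limit), limit) + limit) / (2 * limit)
  rgb <- ramp(scaled)
  colors[ok] <- grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
  list(table = tab, row_clusters = row_clusters,
       separators = as.integer(separators), colors = colors, limit = limit)
}
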