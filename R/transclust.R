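#' Weighted cluster-editing cost of a partition
#'
#' The transitivity-clustering objective: for every unordered pair, the
#' similarity `s` is compared with the threshold `t`; co-clustered pairs
#' with `s < t` cost `t - s` and separated pairs with `s > t` cost `s - t`.
#' A partition whose co-membership agrees with the sign of `s - t`
#' everywhere has cost 0 (the similarity graph is already transitive).
#'
#' @param s symmetric similarity matrix with dimnames
#' @param labels integer cluster labels named by node id (or a
#'   `cluster_assignment`)
#' @param threshold similarity cutpoint
#' @return total editing cost
#' @export
cluster_editing_cost <- function(s, labels, threshold) {
  if (inherits(labels, "cluster_assignment")) labels <- labels$labels
  ids <- rownames(s)
  lab <- labels[ids]
  n <- length(ids)
  cost <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      same <- !is.na(lab[i]) && !is.na(lab[j]) && lab[i] == lab[j]
      sv <- s[i, j]
      if (same && sv < threshold) cost <- cost + (threshold - sv)
      if (!same && sv > threshold) cost <- cost + (sv - threshold)
    }
  }
  cost
}

# enumerate set partitions of n elements as restricted-growth strings,
# calling fn(labels) for each
enumerate_partitions <- function(n, fn) {
  labels <- integer(n)
  recurse <- function(i, maxlab) {
    if (i > n) { fn(labels); return(invisible()) }
    for (l in seq_len(maxlab + 1L)) {
      labels[i] <<- l
      recurse(i + 1L, max(maxlab, l))
    }
  }
  recurse(1L, 0L)
}

#' Transitivity clustering (weighted cluster editing)
#'
#' Finds a partition minimizing the cluster-editing cost
#' ([cluster_editing_cost()]).  Instances with at most `exact_limit` nodes
#' are solved exactly by exhaustive set-partition enumeration.  Larger
#' instances use the documented heuristic: initialize with the
#' single-linkage components of the graph of pairs with similarity above
#' the threshold, then repeatedly apply the best cost-lowering single-node
#' move (to another cluster or to a new singleton; nodes scanned in
#' lexicographic order) until no move improves the cost.
#'
#' @param s symmetric similarity matrix with dimnames
#' @param threshold similarity cutpoint defining the edit costs
#' @param exact_limit exhaustive-search size bound (<= 10)
#' @return a [cluster_assignment()]; attributes `"cost"` and `"exact"`
#' @export
cluster_transclust <- function(s, threshold, exact_limit = 8) {
  s <- as.matrix(s)
  if (nrow(s) != ncol(s)) stop_data("similarity matrix must be square")
  if (max(abs(s - t(s))) > 1e-8) stop_data("similarity matrix must be symmetric")
  if (exact_limit > 10) stop_config("exact_limit must be <= 10")
  if (is.null(rownames(s))) {
    rownames(s) <- colnames(s) <- paste0("N", seq_len(nrow(s)))
  }
  ord <- lex_order(rownames(s))
  s <- s[ord, ord, drop = FALSE]
  ids <- rownames(s)
  n <- length(ids)

  if (n <= exact_limit) {
    best_cost <- Inf
    best_labels <- NULL
    enumerate_partitions(n, function(lab) {
      cost <- partition_cost_fast(s, lab, threshold)
      if (cost < best_cost) {
        best_cost <<- cost
        best_labels <<- lab
      }
    })
    labels <- stats::setNames(best_labels, ids)
    res <- assignment_from_labels(labels)
    attr(res, "cost") <- best_cost
    attr(res, "exact") <- TRUE
    return(res)
  }

  # heuristic: single-linkage components above threshold
  above <- s > threshold
  diag(above) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(above, mode = "undirected")
  lab <- as.integer(igraph::components(g)$membership)

  # pairwise cost contributions: together[i,j] if co-clustered, apart otherwise
  together <- pmax(threshold - s, 0)
  apart <- pmax(s - threshold, 0)
  diag(together) <- 0
  diag(apart) <- 0

  repeat {
    best_delta <- -1e-12
    best_move <- NULL
    next_label <- max(lab) + 1L
    for (v in seq_len(n)) {       # ids already in lexicographic order
      cur <- lab[v]
      mates <- which(lab == cur); mates <- mates[mates != v]
      # cost of v's pairs in the current configuration
      base <- sum(together[v, mates]) + sum(apart[v, -c(v, mates)])
      targets <- c(setdiff(unique(lab), cur), next_label)
      for (tgt in targets) {
        new_mates <- which(lab == tgt)
        new_cost <- sum(together[v, new_mates]) + sum(apart[v, -c(v, new_mates)])
        delta <- base - new_cost
        if (delta > best_delta + 1e-12) {
          best_delta <- delta
          best_move <- c(v, tgt)
        }
      }
    }
    if (is.null(best_move)) break
    lab[best_move[1]] <- best_move[2]
  }
  labels <- stats::setNames(lab, ids)
  res <- assignment_from_labels(labels)
  attr(res, "cost") <- cluster_editing_cost(s, labels, threshold)
  attr(res, "exact") <- FALSE
  res
}

# vectorized cost for an unnamed label vector aligned with rownames(s)
partition_cost_fast <- function(s, lab, threshold) {
  same <- outer(lab, lab, "==")
  ut <- upper.tri(s)
  sum(pmax(threshold - s, 0)[ut & same]) + sum(pmax(s - threshold, 0)[ut & !same])
}
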