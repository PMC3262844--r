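#' Connected components clustering
#'
#' Each connected component becomes one cluster (isolated nodes are
#' singletons); the simplest division of an interaction network.
#' @param network a `weighted_network`
#' @return a [cluster_assignment()]
#' @export
cluster_connected_components <- function(network) {
  if (n_nodes(network) == 0L) return(cluster_assignment(list()))
  g <- as_igraph(network)
  comp <- igraph::components(g)
  labels <- stats::setNames(comp$membership, igraph::V(g)$name)
  assignment_from_labels(labels)
}

#' Newman-Girvan modularity of a partition
#'
#' Q = sum over communities of (e_c / m - (d_c / 2m)^2), where e_c counts
#' intra-community edges, d_c sums member degrees and m is the total edge
#' count; edge weights are ignored.  Q of an edgeless network is defined as
#' 0, as is Q of the one-community partition.
#' @param network a `weighted_network`
#' @param assignment a `cluster_assignment` covering the network's nodes
#' @return numeric modularity
#' @export
modularity_score <- function(network, assignment) {
  m <- n_edges(network)
  if (m == 0L) return(0)
  labels <- assignment$labels
  ed <- network$edges
  deg <- table(factor(c(ed$source, ed$target), levels = network$nodes))
  q <- 0
  for (c in seq_along(assignment$clusters)) {
    members <- assignment$clusters[[c]]
    e_c <- sum(ed$source %in% members & ed$target %in% members)
    d_c <- sum(deg[members])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

#' Girvan-Newman community detection
#'
#' Iteratively removes the edge of highest betweenness (recomputed after
#' every removal; ties broken by the lexicographically smallest edge id),
#' recording the connected-component partition at every distinct component
#' count, and returns the recorded partition of maximal modularity Q
#' (computed on the original network).  Weights are ignored.
#'
#' @param network a `weighted_network`
#' @return a [cluster_assignment()]; attributes `"Q"` (the selected
#'   modularity) and `"levels"` (data.frame of n_communities and Q for every
#'   recorded level)
#' @export
cluster_girvan_newman <- function(network) {
  if (n_nodes(network) == 0L) stop_data("Girvan-Newman requires at least one node")
  ids <- network$nodes
  if (n_edges(network) == 0L) {
    res <- assignment_from_labels(stats::setNames(seq_along(ids), ids))
    attr(res, "Q") <- 0
    attr(res, "levels") <- data.frame(n_communities = length(ids), Q = 0)
    return(res)
  }
  g <- as_igraph(network, weighted = FALSE)

  record <- list()
  seen_counts <- integer(0)
  snapshot <- function(g) {
    comp <- igraph::components(g)
    if (!(comp$no %in% seen_counts)) {
      seen_counts <<- c(seen_counts, comp$no)
      record[[length(record) + 1L]] <<- stats::setNames(comp$membership,
                                                        igraph::V(g)$name)
    }
  }
  snapshot(g)
  while (igraph::ecount(g) > 0L) {
    eb <- igraph::edge_betweenness(g, directed = FALSE)
    ends <- igraph::ends(g, igraph::E(g))
    keys <- pair_key(ends[, 1], ends[, 2])
    cand <- which(eb >= max(eb) - 1e-10)
    pick <- cand[lex_order(keys[cand])[1]]
    g <- igraph::delete_edges(g, pick)
    snapshot(g)
  }

  qs <- numeric(length(record))
  assignments <- vector("list", length(record))
  for (i in seq_along(record)) {
    assignments[[i]] <- assignment_from_labels(record[[i]])
    qs[i] <- modularity_score(network, assignments[[i]])
  }
  best <- which.max(qs)
  res <- assignments[[best]]
  attr(res, "Q") <- qs[best]
  attr(res, "levels") <- data.frame(n_communities = seen_counts, Q = qs)
  res
}
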