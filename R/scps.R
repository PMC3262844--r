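#' Spectral clustering of similarity networks (SCPS-style)
#'
#' Degree-normalizes the similarity matrix to D^(-1/2) S D^(-1/2), takes its
#' leading eigenvectors, row-normalizes the embedding to unit length, and
#' partitions it with seeded k-means restarts.  With `n_clusters = "auto"`
#' the number of clusters is the position of the largest gap in the sorted
#' eigenvalue sequence, excluding the trivial leading eigenvalue; when no
#' non-trivial gap exists (all remaining eigenvalues essentially equal) a
#' single cluster is returned.  Zero-degree nodes are split off as
#' singletons before embedding.
#'
#' @param s symmetric non-negative similarity matrix with dimnames
#' @param n_clusters integer, or `"auto"` for eigengap selection
#' @param kmeans_restarts number of seeded k-means restarts
#' @param seed integer seed controlling the restarts
#' @return a [cluster_assignment()]; attributes `"k"` (clusters used for the
#'   embedded nodes) and `"eigenvalues"`
#' @export
cluster_scps <- function(s, n_clusters = "auto", kmeans_restarts = 10, seed = 42) {
  s <- as.matrix(s)
  if (nrow(s) != ncol(s)) stop_data("similarity matrix must be square")
  if (max(abs(s - t(s))) > 1e-8) stop_data("similarity matrix must be symmetric")
  if (any(s < 0)) stop_data("similarities must be non-negative")
  if (is.null(rownames(s))) {
    rownames(s) <- colnames(s) <- paste0("N", seq_len(nrow(s)))
  }
  ids <- rownames(s)

  deg <- rowSums(s)
  isolated <- ids[deg == 0]
  keep <- ids[deg > 0]
  if (length(keep) == 0L) {
    return(assignment_from_labels(stats::setNames(seq_along(ids), ids)))
  }
  sk <- s[keep, keep, drop = FALSE]
  dk <- deg[keep]
  inv_sqrt <- 1 / sqrt(dk)
  L <- sk * outer(inv_sqrt, inv_sqrt)
  eig <- eigen((L + t(L)) / 2, symmetric = TRUE)
  ev <- eig$values  # descending

  n <- length(keep)
  if (identical(n_clusters, "auto")) {
    if (n < 3L) {
      k <- 1L
    } else {
      gaps <- ev[-n] - ev[-1]
      cand <- gaps[-1]              # exclude the trivial leading gap
      if (max(cand) <= 1e-8) {
        k <- 1L
      } else {
        k <- which.max(cand) + 1L
      }
    }
  } else {
    if (!is_count(n_clusters)) stop_config("n_clusters must be a positive integer or 'auto'")
    k <- min(as.integer(n_clusters), n)
  }

  if (k == 1L) {
    labels <- stats::setNames(rep(1L, n), keep)
  } else {
    U <- eig$vectors[, seq_len(k), drop = FALSE]
    norms <- sqrt(rowSums(U^2))
    norms[norms == 0] <- 1
    U <- U / norms
    rownames(U) <- keep
    km <- lloyd_kmeans(U, k, metric = "euclidean", n_init = kmeans_restarts,
                       max_iterations = 100, seed = seed)
    labels <- km$labels
  }
  if (length(isolated) > 0L) {
    labels <- c(labels, stats::setNames(max(labels) + seq_along(isolated), isolated))
  }
  res <- assignment_from_labels(labels)
  attr(res, "k") <- k
  attr(res, "eigenvalues") <- ev
  res
}
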