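# Internal seeded Lloyd k-means over matrix rows, used by cluster_kmeans and
# the SCPS embedding step.  Missing values: assignment distances use shared
# columns, centers are per-column means over non-missing member entries.
lloyd_kmeans <- function(X, k, metric = "euclidean", n_init = 10,
                         max_iterations = 100, seed = 42) {
  n <- nrow(X)
  p <- ncol(X)
  ids <- rownames(X)
  best <- NULL
  for (init in seq_len(n_init)) {
    idx <- withr::with_seed(seed + init - 1L, sample.int(n, k))
    centers <- X[idx, , drop = FALSE]
    labels <- rep(0L, n)
    history <- numeric(0)
    history_sq <- numeric(0)
    for (iter in seq_len(max_iterations)) {
      d2c <- matrix(NA_real_, n, k)
      for (c in seq_len(k)) {
        for (i in seq_len(n)) {
          d2c[i, c] <- pair_distance(X[i, ], centers[c, ], metric, p_total = p)
        }
      }
      d2c[is.na(d2c)] <- Inf
      new_labels <- max.col(-d2c, ties.method = "first")
      # repair empty clusters with the row farthest from its center
      empty <- setdiff(seq_len(k), unique(new_labels))
      for (c in empty) {
        dist_own <- d2c[cbind(seq_len(n), new_labels)]
        cand <- which.max(ifelse(tabulate(new_labels, k)[new_labels] > 1, dist_own, -Inf))
        new_labels[cand] <- c
      }
      own <- d2c[cbind(seq_len(n), new_labels)]
      history <- c(history, sum(own))
      history_sq <- c(history_sq, sum(own^2))  # the Lloyd energy under mean updates
      converged <- identical(new_labels, labels)
      labels <- new_labels
      for (c in seq_len(k)) {
        members <- X[labels == c, , drop = FALSE]
        centers[c, ] <- colMeans(members, na.rm = TRUE)
      }
      centers[is.nan(centers)] <- NA_real_
      if (converged) break
    }
    obj <- 0
    for (i in seq_len(n)) {
      di <- pair_distance(X[i, ], centers[labels[i], ], metric, p_total = p)
      obj <- obj + if (is.na(di)) 0 else di
    }
    if (is.null(best) || obj < best$objective - 1e-12) {
      best <- list(labels = stats::setNames(labels, ids), centers = centers,
                   objective = obj, history = history, history_sq = history_sq)
    }
  }
  best
}

#' k-means clustering of matrix rows
#'
#' Lloyd iterations under any of the package's distance metrics: rows are
#' assigned to the nearest center (ties to the lowest cluster index) and
#' centers are recomputed as per-column means over non-missing member
#' values (arithmetic-mean centroids are used even for correlation-family
#' metrics, following Cluster 3.0).  The best of `n_init` seeded random
#' initializations (distinct rows as starting centers) by total
#' within-cluster distance is returned.  Rows with no data are excluded and
#' reported as unassigned.
#'
#' @param matrix an `attribute_matrix` or numeric matrix with rownames
#' @param k number of clusters
#' @param metric distance metric (see [compute_distance()])
#' @param n_init number of seeded restarts
#' @param max_iterations Lloyd iteration cap per restart
#' @param seed integer seed
#' @return a [cluster_assignment()]; attributes `"centers"` (k x p matrix),
#'   `"wcss"` (total within-cluster distance), `"history"` (that objective
#'   per Lloyd iteration of the winning restart) and `"history_sq"` (the
#'   sum of squared distances, the energy the mean-update step minimizes
#'   and hence the quantity guaranteed non-increasing under `euclidean`)
#' @export
cluster_kmeans <- function(matrix, k, metric = "euclidean", n_init = 10,
                           max_iterations = 100, seed = 42) {
  v <- if (inherits(matrix, "attribute_matrix")) matrix$values else as.matrix(matrix)
  drop_ids <- rows_all_missing(v)
  X <- v[setdiff(rownames(v), drop_ids), , drop = FALSE]
  if (!is_count(k)) stop_config("k must be a positive integer")
  if (k > nrow(X)) stop_config("k (", k, ") exceeds the number of clusterable rows (",
                               nrow(X), ")")
  fit <- lloyd_kmeans(X, as.integer(k), metric = metric, n_init = n_init,
                      max_iterations = max_iterations, seed = seed)
  res <- assignment_from_labels(c(fit$labels,
                                  stats::setNames(rep(NA_integer_, length(drop_ids)),
                                                  drop_ids)))
  attr(res, "centers") <- fit$centers
  attr(res, "wcss") <- fit$objective
  attr(res, "history") <- fit$history
  attr(res, "history_sq") <- fit$history_sq
  res
}

#' k-medoid clustering of matrix rows
#'
#' As [cluster_kmeans()], but centers are restricted to actual rows: the
#' update step picks the member minimizing the summed distance to its
#' cluster (ties to the lexicographically smallest id).
#'
#' @inheritParams cluster_kmeans
#' @return a [cluster_assignment()]; attributes `"medoids"` (row ids),
#'   `"wcss"`
#' @export
cluster_kmedoid <- function(matrix, k, metric = "euclidean", n_init = 10,
                            max_iterations = 100, seed = 42) {
  v <- if (inherits(matrix, "attribute_matrix")) matrix$values else as.matrix(matrix)
  drop_ids <- rows_all_missing(v)
  X <- v[setdiff(rownames(v), drop_ids), , drop = FALSE]
  if (!is_count(k)) stop_config("k must be a positive integer")
  n <- nrow(X)
  if (k > n) stop_config("k (", k, ") exceeds the number of clusterable rows (", n, ")")
  ids <- rownames(X)
  D <- compute_distance(X, metric)$d

  best <- NULL
  for (init in seq_len(n_init)) {
    medoids <- withr::with_seed(seed + init - 1L, sample.int(n, k))
    labels <- rep(0L, n)
    for (iter in seq_len(max_iterations)) {
      d2m <- D[, medoids, drop = FALSE]
      new_labels <- max.col(-d2m, ties.method = "first")
      new_labels[medoids] <- seq_len(k)   # medoids stay in their own cluster
      empty <- setdiff(seq_len(k), unique(new_labels))
      for (c in empty) {
        dist_own <- d2m[cbind(seq_len(n), new_labels)]
        cand <- which.max(ifelse(tabulate(new_labels, k)[new_labels] > 1, dist_own, -Inf))
        new_labels[cand] <- c
        medoids[c] <- cand
      }
      converged <- identical(new_labels, labels)
      labels <- new_labels
      for (c in seq_len(k)) {
        members <- which(labels == c)
        sums <- colSums(D[members, members, drop = FALSE])
        medoids[c] <- members[which.min(sums)]  # ids sorted: ties -> smallest id
      }
      if (converged) break
    }
    obj <- sum(D[cbind(seq_len(n), medoids[labels])])
    if (is.null(best) || obj < best$objective - 1e-12) {
      best <- list(labels = stats::setNames(labels, ids),
                   medoids = ids[medoids], objective = obj)
    }
  }
  res <- assignment_from_labels(c(best$labels,
                                  stats::setNames(rep(NA_integer_, length(drop_ids)),
                                                  drop_ids)))
  attr(res, "medoids") <- best$medoids
  attr(res, "wcss") <- best$objective
  res
}

#' Silhouette widths of a partition
#'
#' s(i) = (b - a) / max(a, b), with a the mean distance to i's own cluster
#' (excluding i) and b the smallest mean distance to any other cluster.
#' Members of singleton clusters get s = 0 by convention, as do nodes with
#' a = b = 0.
#'
#' @param assignment a `cluster_assignment` with at least 2 clusters
#' @param distance a `distance_matrix` (or plain symmetric matrix with
#'   dimnames) covering the assigned nodes
#' @return list with `widths` (named numeric) and `mean`
#' @export
silhouette_widths <- function(assignment, distance) {
  D <- if (inherits(distance, "distance_matrix")) distance$d else as.matrix(distance)
  if (n_clusters(assignment) < 2L) {
    stop_data("silhouette is undefined for a single-cluster partition")
  }
  clusters <- assignment$clusters
  nodes <- unlist(clusters, use.names = FALSE)
  widths <- stats::setNames(numeric(length(nodes)), nodes)
  for (ci in seq_along(clusters)) {
    members <- clusters[[ci]]
    for (v in members) {
      if (length(members) == 1L) { widths[v] <- 0; next }
      a <- mean(D[v, setdiff(members, v)])
      b <- min(vapply(clusters[-ci], function(other) mean(D[v, other]), numeric(1)))
      denom <- max(a, b)
      widths[v] <- if (denom == 0) 0 else (b - a) / denom
    }
  }
  list(widths = widths, mean = mean(widths))
}

#' Choose k by maximizing the average silhouette
#'
#' Runs k-means or k-medoid for every k in `k_range` with a shared seed and
#' returns the k of maximal mean silhouette width (ties to the smaller k),
#' the standard model-selection rule for partitional clustering of
#' expression profiles.
#'
#' @inheritParams cluster_kmeans
#' @param algorithm `"kmeans"` or `"kmedoid"`
#' @param k_range integer vector `c(k_min, k_max)` with `k_min >= 2`
#' @return list with `k` (chosen), `silhouettes` (data.frame of k and mean
#'   silhouette) and `assignment` (the winning partition)
#' @export
select_k <- function(matrix, algorithm = c("kmeans", "kmedoid"), k_range = c(2, 5),
                     metric = "euclidean", n_init = 10, max_iterations = 100,
                     seed = 42) {
  algorithm <- match.arg(algorithm)
  v <- if (inherits(matrix, "attribute_matrix")) matrix$values else as.matrix(matrix)
  X <- v[setdiff(rownames(v), rows_all_missing(v)), , drop = FALSE]
  k_min <- k_range[1]; k_max <- k_range[2]
  if (k_min < 2 || k_max > nrow(X) - 1 || k_min > k_max) {
    stop_config("k_range must lie within [2, rows - 1]")
  }
  D <- compute_distance(X, metric)
  fn <- if (algorithm == "kmeans") cluster_kmeans else cluster_kmedoid
  ks <- seq.int(k_min, k_max)
  sil <- numeric(length(ks))
  fits <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    fits[[i]] <- fn(X, ks[i], metric = metric, n_init = n_init,
                    max_iterations = max_iterations, seed = seed)
    sil[i] <- silhouette_widths(fits[[i]], D)$mean
  }
  best <- which.max(sil)  # which.max takes the first maximum: ties -> smaller k
  list(k = ks[best],
       silhouettes = data.frame(k = ks, mean_silhouette = sil),
       assignment = fits[[best]])
}
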