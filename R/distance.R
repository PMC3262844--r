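#' @keywords internal
DISTANCE_METRICS <- c("euclidean", "cityblock", "pearson", "pearson_abs",
                      "uncentered", "uncentered_abs", "spearman", "kendall")

CORRELATION_METRICS <- c("pearson", "pearson_abs", "uncentered", "uncentered_abs",
                         "spearman", "kendall")

# Distance between two profiles under a named metric with pairwise-complete
# missing-value semantics (Cluster 3.0 convention).  p_total is the nominal
# profile length; euclidean/cityblock sums are rescaled by p_total/shared so
# distances remain comparable across different missingness patterns.
pair_distance <- function(x, y, metric, p_total = length(x)) {
  shared <- which(!is.na(x) & !is.na(y))
  m <- length(shared)
  if (metric %in% CORRELATION_METRICS) {
    if (m < 2L) return(NA_real_)  # caller substitutes the maximal distance 2
    xs <- x[shared]; ys <- y[shared]
    r <- switch(metric,
      pearson = , pearson_abs = {
        if (stats::sd(xs) == 0 || stats::sd(ys) == 0) 0 else stats::cor(xs, ys)
      },
      uncentered = , uncentered_abs = {
        den <- sqrt(sum(xs^2) * sum(ys^2))
        if (den == 0) 0 else sum(xs * ys) / den
      },
      spearman = {
        if (length(unique(xs)) < 2L || length(unique(ys)) < 2L) 0
        else stats::cor(xs, ys, method = "spearman")
      },
      kendall = {
        if (length(unique(xs)) < 2L || length(unique(ys)) < 2L) 0
        else stats::cor(xs, ys, method = "kendall")
      })
    if (is.na(r)) r <- 0
    d <- if (grepl("_abs$", metric)) 1 - abs(r) else 1 - r
    return(min(max(d, 0), 2))
  }
  if (m < 1L) return(NA_real_)
  xs <- x[shared]; ys <- y[shared]
  switch(metric,
    euclidean = sqrt(sum((xs - ys)^2) * p_total / m),
    cityblock = sum(abs(xs - ys)) * p_total / m)
}

#' Pairwise distance matrix of matrix rows or columns
#'
#' Supported metrics: `euclidean`, `cityblock`, and the correlation family
#' `pearson`, `pearson_abs`, `uncentered`, `uncentered_abs`, `spearman`,
#' `kendall` (distance is 1 - r, or 1 - |r| for the `_abs` variants, hence
#' in \[0, 2\]).  Uncentered correlation is the cosine of the raw profiles,
#' the conventional metric for EMAP-style matrices.  Missing values follow
#' pairwise-complete semantics; a pair with fewer than 2 shared observations
#' under a correlation metric gets the maximal distance 2 with a warning,
#' and a zero-variance profile under `pearson` gets r = 0 (distance 1).
#'
#' @param matrix an `attribute_matrix` or numeric matrix with dimnames
#' @param metric metric name (see above)
#' @param axis `"rows"` (default) or `"cols"`
#' @return object of class `distance_matrix`: `ids`, symmetric matrix `d`
#'   with zero diagonal, and `metric`
#' @examples
#' m <- matrix(c(1, 2, 3, 3, 2, 1), 2, byrow = TRUE,
#'             dimnames = list(c("a", "b"), NULL))
#' compute_distance(m, "pearson")$d["a", "b"]  # 2: perfectly anticorrelated
#' @export
compute_distance <- function(matrix, metric = DISTANCE_METRICS, axis = c("rows", "cols")) {
  metric <- match.arg(metric)
  axis <- match.arg(axis)
  v <- if (inherits(matrix, "attribute_matrix")) matrix$values else as.matrix(matrix)
  if (axis == "cols") v <- t(v)
  ids <- rownames(v)
  if (is.null(ids)) ids <- paste0("R", seq_len(nrow(v)))
  n <- nrow(v)
  p <- ncol(v)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  n_degenerate <- 0L
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      xi <- v[i, ]
      for (j in (i + 1L):n) {
        dij <- pair_distance(xi, v[j, ], metric, p_total = p)
        if (is.na(dij)) {
          n_degenerate <- n_degenerate + 1L
          dij <- if (metric %in% CORRELATION_METRICS) 2 else NA_real_
        }
        d[i, j] <- dij
        d[j, i] <- dij
      }
    }
  }
  if (anyNA(d)) {
    # pairs with no shared observations under a non-correlation metric:
    # substitute the largest finite distance observed
    mx <- suppressWarnings(max(d, na.rm = TRUE))
    if (!is.finite(mx)) mx <- 0
    d[is.na(d)] <- mx
  }
  if (n_degenerate > 0L) {
    warning(n_degenerate, " pair(s) with insufficient shared observations were ",
            "assigned the maximal distance", call. = FALSE)
  }
  structure(list(ids = ids, d = d, metric = metric), class = "distance_matrix")
}

#' @export
as.matrix.distance_matrix <- function(x, ...) x$d

#' @export
as.dist.distance_matrix <- function(m, ...) stats::as.dist(m$d)

#' @export
print.distance_matrix <- function(x, ...) {
  cat("distance_matrix:", length(x$ids), "items, metric =", x$metric, "\n")
  invisible(x)
}
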