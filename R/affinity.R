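#' Affinity propagation
#'
#' Frey-Dueck message passing on a similarity matrix.  Responsibilities and
#' availabilities are updated with damping until the exemplar set has been
#' stable for `convergence_window` consecutive iterations (or
#' `max_iterations` is reached).  The diagonal is overwritten by the
#' preference; `"median"` uses the median off-diagonal similarity, the usual
#' default yielding a moderate number of clusters.  Every node is assigned
#' to the exemplar with the highest similarity; exemplars are assigned to
#' themselves.  The update is fully deterministic.
#'
#' @param s square similarity matrix with identical row/column names
#' @param preference numeric self-similarity, or `"median"`
#' @param damping damping factor in \[0.5, 1)
#' @param max_iterations iteration cap
#' @param convergence_window iterations of exemplar stability required
#' @return a [cluster_assignment()]; attribute `"exemplars"` holds the
#'   exemplar ids (one per cluster)
#' @export
cluster_ap <- function(s, preference = "median", damping = 0.9,
                       max_iterations = 1000, convergence_window = 50) {
  s <- as.matrix(s)
  if (nrow(s) != ncol(s)) stop_data("similarity matrix must be square")
  if (is.null(rownames(s))) {
    rownames(s) <- colnames(s) <- paste0("N", seq_len(nrow(s)))
  }
  if (!identical(rownames(s), colnames(s))) stop_data("row/column names must match")
  if (damping < 0.5 || damping >= 1) stop_config("damping must be in [0.5, 1)")
  ids <- rownames(s)
  n <- nrow(s)
  if (n == 1L) {
    res <- cluster_assignment(list(ids))
    attr(res, "exemplars") <- ids
    return(res)
  }
  pref <- if (identical(preference, "median")) {
    stats::median(s[row(s) != col(s)])
  } else {
    as.numeric(preference)
  }
  S <- s
  diag(S) <- pref

  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  stable <- 0L
  last_ex <- integer(0)
  for (iter in seq_len(max_iterations)) {
    # responsibilities
    AS <- A + S
    max1 <- apply(AS, 1, max)
    idx1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), idx1)] <- -Inf
    max2 <- apply(AS2, 1, max)
    Mx <- matrix(max1, n, n)
    Mx[cbind(seq_len(n), idx1)] <- max2
    R <- damping * R + (1 - damping) * (S - Mx)

    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- 0
    cs <- colSums(Rp)
    Anew <- matrix(diag(R), n, n, byrow = TRUE) + matrix(cs, n, n, byrow = TRUE) - Rp
    Anew <- pmin(Anew, 0)
    diag(Anew) <- cs
    A <- damping * A + (1 - damping) * Anew

    ex <- which(diag(A) + diag(R) > 0)
    if (identical(ex, last_ex) && length(ex) > 0L) {
      stable <- stable + 1L
      if (stable >= convergence_window) break
    } else {
      stable <- 0L
      last_ex <- ex
    }
  }
  ex <- which(diag(A) + diag(R) > 0)
  if (length(ex) == 0L) ex <- which.max(diag(A) + diag(R))
  # each node joins the exemplar of maximal similarity; exemplars to themselves
  assign_idx <- apply(S[, ex, drop = FALSE], 1, which.max)
  assign_idx[ex] <- seq_along(ex)
  labels <- stats::setNames(assign_idx, ids)
  res <- assignment_from_labels(labels)
  attr(res, "exemplars") <- ids[ex]
  res
}
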