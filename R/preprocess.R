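#' Convert edge weights
#'
#' Network-clustering algorithms expect similarities; raw edge attributes
#' are often e-values or other "smaller is better" scores.  `neg_log10`
#' (the conversion used for BLAST e-values, where a cutoff of 6 corresponds
#' to 1e-6) maps weight w to -log10(w); `reciprocal` to 1/w; `log10` to
#' log10(w); `none` is the identity.
#'
#' @param network a `weighted_network`
#' @param mode one of `"none"`, `"neg_log10"`, `"reciprocal"`, `"log10"`
#' @param clamp_nonpositive under the log modes, clamp non-positive weights
#'   (e.g. e-values reported as 0) to the smallest positive double instead
#'   of erroring; the clamping is reported.
#' @return the converted network (node set unchanged)
#' @export
convert_weights <- function(network, mode = c("none", "neg_log10", "reciprocal", "log10"),
                            clamp_nonpositive = TRUE) {
  mode <- match.arg(mode)
  if (mode == "none" || n_edges(network) == 0L) return(network)
  w <- network$edges$weight
  if (mode %in% c("neg_log10", "log10")) {
    bad <- w <= 0
    if (any(bad)) {
      if (!clamp_nonpositive) {
        i <- which(bad)[1]
        stop_data("non-positive weight on edge ", network$edges$source[i], "--",
                  network$edges$target[i], " under ", mode, " conversion")
      }
      ck_message("clamped ", sum(bad), " non-positive weight(s) to the smallest ",
                 "positive double before ", mode)
      w[bad] <- .Machine$double.xmin
    }
    w <- if (mode == "neg_log10") -log10(w) else log10(w)
  } else if (mode == "reciprocal") {
    if (any(w == 0)) {
      i <- which(w == 0)[1]
      stop_data("zero weight on edge ", network$edges$source[i], "--",
                network$edges$target[i], " under reciprocal conversion")
    }
    w <- 1 / w
  }
  network$edges$weight <- w
  network
}

#' Histogram of edge weights
#'
#' Equal-width bins spanning the weight range; bins are right-closed and the
#' first bin includes its left edge, so every edge is counted exactly once.
#' A degenerate range (all weights equal) is widened by +/-0.5 to avoid
#' zero-width bins.
#'
#' @param network a `weighted_network` with at least one edge
#' @param n_bins number of bins (>= 2)
#' @param conversion label recorded on the histogram (bookkeeping only)
#' @return object of class `weight_histogram`: `bin_edges` (length
#'   `n_bins + 1`), `counts`, `conversion`
#' @export
edge_weight_histogram <- function(network, n_bins = 100, conversion = "none") {
  if (n_edges(network) == 0L) stop_data("cannot histogram a network with no edges")
  if (!is_count(n_bins) || n_bins < 2) stop_config("n_bins must be an integer >= 2")
  w <- network$edges$weight
  lo <- min(w); hi <- max(w)
  if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  idx <- .bincode(w, breaks = edges, right = TRUE, include.lowest = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_edges = edges, counts = counts, conversion = conversion),
            class = "weight_histogram")
}

#' @export
print.weight_histogram <- function(x, ...) {
  cat("weight_histogram:", length(x$counts), "bins over [",
      format(x$bin_edges[1]), ",", format(x$bin_edges[length(x$bin_edges)]),
      "],", sum(x$counts), "edges\n")
  invisible(x)
}

#' Export a histogram as a two-column TSV (bin_left, count)
#' @param histogram a `weight_histogram`
#' @param path output path
#' @export
write_histogram <- function(histogram, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("bin_left\tcount", con, sep = "\n")
  n <- length(histogram$counts)
  for (i in seq_len(n)) {
    writeLines(sprintf("%.17g\t%d", histogram$bin_edges[i], histogram$counts[i]),
               con, sep = "\n")
  }
  invisible(path)
}

#' Histogram-based edge-weight cutoff heuristic
#'
#' Similarity-weight distributions of all-vs-all comparisons typically show
#' a large noise peak at low weight followed by a valley before the signal.
#' The heuristic smooths the counts with a centered moving average of window
#' 3, locates the global maximum bin, and returns the left edge of the first
#' strict local minimum after it.  When no interior minimum exists (monotone
#' count profiles) it falls back to the weight at which the cumulative edge
#' count reaches 90%.  The heuristic is pluggable: any function
#' `f(histogram) -> numeric` can be registered via the `fn` argument of the
#' pipeline; this is the documented default.
#'
#' @param histogram a `weight_histogram` with at least 5 bins
#' @return a single cutoff value (a weight)
#' @export
heuristic_cutoff <- function(histogram) {
  counts <- histogram$counts
  n <- length(counts)
  if (n < 5L) stop_config("heuristic_cutoff needs >= 5 bins; re-bin the histogram")
  sm <- vapply(seq_len(n), function(i) {
    mean(counts[max(1L, i - 1L):min(n, i + 1L)])
  }, numeric(1))
  peak <- which.max(sm)
  if (peak < n) {
    # compress plateaus so a run of equal smoothed counts (e.g. empty bins
    # between the noise peak and the signal mass) acts as one candidate valley
    post <- sm[peak:n]
    change <- c(TRUE, diff(post) != 0)
    seg_start <- which(change)                 # first bin of each segment
    seg_val <- post[seg_start]
    if (length(seg_val) >= 3L) {
      for (i in 2L:(length(seg_val) - 1L)) {
        if (seg_val[i] < seg_val[i - 1L] && seg_val[i] < seg_val[i + 1L]) {
          return(histogram$bin_edges[peak + seg_start[i] - 1L])
        }
      }
    }
  }
  # fallback: right edge of the bin where cumulative count reaches 90%
  cum <- cumsum(counts)
  j <- which(cum >= 0.9 * sum(counts))[1]
  histogram$bin_edges[j + 1L]
}

#' Remove edges below a weight cutoff
#'
#' Edges with weight strictly below the cutoff are removed (>= keeps the
#' edge, matching the usual "PE cutoff" semantics); nodes are retained and
#' may become isolated.  Monotone: raising the cutoff only shrinks the edge
#' set.
#' @param network a `weighted_network`
#' @param cutoff numeric threshold
#' @return filtered network (same node set)
#' @export
apply_cutoff <- function(network, cutoff) {
  keep <- network$edges$weight >= cutoff
  network$edges <- network$edges[keep, , drop = FALSE]
  rownames(network$edges) <- NULL
  network
}

#' Symmetric adjacency matrix from an edge attribute
#'
#' Builds the dense node-by-node matrix used to feed attribute-clustering
#' algorithms with a single edge attribute, and the similarity-matrix
#' algorithms (AP, TransClust, SCPS).
#' @param network a `weighted_network`
#' @param missing_value value for node pairs with no edge (default 0)
#' @param diagonal value for the diagonal (default 0)
#' @return numeric matrix with node ids as dimnames
#' @export
adjacency_from_edge_attribute <- function(network, missing_value = 0, diagonal = 0) {
  ids <- network$nodes
  n <- length(ids)
  A <- matrix(missing_value, n, n, dimnames = list(ids, ids))
  ed <- network$edges
  if (nrow(ed) > 0L) {
    i <- match(ed$source, ids); j <- match(ed$target, ids)
    A[cbind(i, j)] <- ed$weight
    A[cbind(j, i)] <- ed$weight
  }
  diag(A) <- diagonal
  A
}
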