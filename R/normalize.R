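#' Normalize an expression matrix
#'
#' Applies the requested steps in order.  `log2` log-transforms (requires
#' positive values), `median_center_rows` / `median_center_cols` subtract
#' the row/column median, and `ss1_rows` / `ss1_cols` rescale each row /
#' column so its sum of squares is 1 (the "Sum of Squares = 1" option of
#' ensemble expression clustering).  Missing values are ignored when
#' computing medians and sums of squares; rows or columns that are entirely
#' missing are left untouched.
#'
#' @param matrix an `attribute_matrix` or numeric matrix with rownames
#' @param steps ordered character vector, subset of `log2`,
#'   `median_center_rows`, `median_center_cols`, `ss1_rows`, `ss1_cols`
#' @return an `attribute_matrix` with the same dimensions
#' @examples
#' m <- attribute_matrix(matrix(c(1, 2, 4), 1, dimnames = list("g1", NULL)))
#' as.matrix(normalize_matrix(m, "log2"))  # 0 1 2
#' @export
normalize_matrix <- function(matrix, steps) {
  known <- c("log2", "median_center_rows", "median_center_cols", "ss1_rows", "ss1_cols")
  steps <- as.character(steps)
  if (!all(steps %in% known)) {
    stop_config("unknown normalization step(s): ",
                paste(setdiff(steps, known), collapse = ", "))
  }
  meta <- if (inherits(matrix, "attribute_matrix")) matrix else NULL
  v <- if (is.null(meta)) as.matrix(matrix) else meta$values

  for (s in steps) {
    if (s == "log2") {
      bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
      if (nrow(bad) > 0L) {
        stop_data("log2 of non-positive value at row '", rownames(v)[bad[1, 1]],
                  "', column '", colnames(v)[bad[1, 2]], "'")
      }
      v <- log2(v)
    } else if (s == "median_center_rows") {
      med <- apply(v, 1, stats::median, na.rm = TRUE)
      med[!is.finite(med)] <- 0
      v <- sweep(v, 1, med, "-")
    } else if (s == "median_center_cols") {
      med <- apply(v, 2, stats::median, na.rm = TRUE)
      med[!is.finite(med)] <- 0
      v <- sweep(v, 2, med, "-")
    } else if (s == "ss1_rows") {
      ss <- sqrt(apply(v, 1, function(x) sum(x^2, na.rm = TRUE)))
      ss[!is.finite(ss) | ss == 0] <- 1
      v <- sweep(v, 1, ss, "/")
    } else if (s == "ss1_cols") {
      ss <- sqrt(apply(v, 2, function(x) sum(x^2, na.rm = TRUE)))
      ss[!is.finite(ss) | ss == 0] <- 1
      v <- sweep(v, 2, ss, "/")
    }
  }
  attribute_matrix(v,
                   name = if (!is.null(meta)) meta$name else NULL,
                   gweight = if (!is.null(meta)) meta$gweight else NULL,
                   eweight = if (!is.null(meta)) meta$eweight else NULL)
}
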