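#' Export a clustered matrix in Java TreeView format (CDT / GTR / ATR)
#'
#' Writes the Cluster 3.0 / Java TreeView file triplet: the CDT holds the
#' data matrix permuted to the dendrogram leaf order, with GID/AID columns
#' referencing the GTR (gene tree) and ATR (array tree) node ids
#' (`GENEnX`, `ARRYnX`, `NODEnX`).  Tree files list one merge per row as
#' `(node, child, child, score)` in merge order.  TreeView expects the
#' score column to be a correlation, so for correlation-family metrics the
#' score is `1 - merge height`; for other metrics `-height` is written and
#' noted in a header comment.  Values are written with 6 significant
#' digits; [read_matrix()] on the CDT restores them exactly at that
#' precision.
#'
#' @param matrix an `attribute_matrix` or numeric matrix with dimnames
#' @param row_dendrogram `hclust` for the rows (leaves = rownames), or NULL
#' @param col_dendrogram optional `hclust` for the columns
#' @param path_prefix output prefix; writes `<prefix>.cdt` and
#'   `<prefix>.gtr` / `<prefix>.atr` as applicable
#' @return invisible character vector of the files written
#' @export
write_treeview <- function(matrix, row_dendrogram = NULL, col_dendrogram = NULL,
                           path_prefix) {
  v <- if (inherits(matrix, "attribute_matrix")) matrix$values else as.matrix(matrix)
  meta <- if (inherits(matrix, "attribute_matrix")) matrix else NULL
  row_ids <- rownames(v); col_ids <- colnames(v)

  check_leaves <- function(tree, ids, what) {
    if (!setequal(tree$labels, ids)) {
      stop_data(what, " dendrogram leaves do not match matrix ", what, " ids")
    }
  }
  files <- character(0)

  score_of <- function(tree) {
    fam <- (tree$dist.method %||% "euclidean") %in% CORRELATION_METRICS
    if (fam) 1 - tree$height else -tree$height
  }
  corr_family <- function(tree) (tree$dist.method %||% "euclidean") %in% CORRELATION_METRICS

  write_tree <- function(tree, ids, leaf_prefix, path) {
    # leaf numbering follows the original matrix order, Cluster 3.0 style
    leaf_id <- stats::setNames(sprintf("%s%dX", leaf_prefix, seq_along(ids) - 1L), ids)
    scores <- score_of(tree)
    con <- file(path, open = "wb")
    on.exit(close(con))
    if (!corr_family(tree)) {
      writeLines(paste0("# score = -merge_height (metric: ",
                        tree$dist.method %||% "unknown", ")"), con, sep = "\n")
    }
    n_merge <- nrow(tree$merge)
    for (s in seq_len(n_merge)) {
      code <- function(x) if (x < 0) leaf_id[tree$labels[-x]] else sprintf("NODE%dX", x)
      writeLines(paste(sprintf("NODE%dX", s), code(tree$merge[s, 1]),
                       code(tree$merge[s, 2]), sprintf("%.6g", scores[s]),
                       sep = "\t"), con, sep = "\n")
    }
    leaf_id
  }

  gene_id <- stats::setNames(sprintf("GENE%dX", seq_along(row_ids) - 1L), row_ids)
  arry_id <- stats::setNames(sprintf("ARRY%dX", seq_along(col_ids) - 1L), col_ids)

  if (!is.null(row_dendrogram)) {
    check_leaves(row_dendrogram, row_ids, "row")
    gtr <- paste0(path_prefix, ".gtr")
    gene_id <- write_tree(row_dendrogram, row_ids, "GENE", gtr)
    files <- c(files, gtr)
    row_order <- row_dendrogram$labels[row_dendrogram$order]
  } else {
    row_order <- row_ids
  }
  if (!is.null(col_dendrogram)) {
    check_leaves(col_dendrogram, col_ids, "col")
    atr <- paste0(path_prefix, ".atr")
    arry_id <- write_tree(col_dendrogram, col_ids, "ARRY", atr)
    files <- c(files, atr)
    col_order <- col_dendrogram$labels[col_dendrogram$order]
  } else {
    col_order <- col_ids
  }

  cdt <- paste0(path_prefix, ".cdt")
  con <- file(cdt, open = "wb")
  has_gid <- !is.null(row_dendrogram)
  has_aid <- !is.null(col_dendrogram)
  lead <- c(if (has_gid) "GID", "UNIQID", "NAME", "GWEIGHT")
  writeLines(paste(c(lead, col_order), collapse = "\t"), con, sep = "\n")
  pad <- length(lead) - 1L
  if (has_aid) {
    writeLines(paste(c("AID", rep("", pad), arry_id[col_order]), collapse = "\t"),
               con, sep = "\n")
  }
  ew <- if (!is.null(meta) && !is.null(meta$eweight)) meta$eweight else rep(1, length(col_ids))
  names(ew) <- col_ids
  writeLines(paste(c("EWEIGHT", rep("", pad), sprintf("%.6g", ew[col_order])),
                   collapse = "\t"), con, sep = "\n")
  gname <- if (!is.null(meta) && !is.null(meta$name)) {
    stats::setNames(meta$name, row_ids)
  } else {
    stats::setNames(row_ids, row_ids)
  }
  gw <- if (!is.null(meta) && !is.null(meta$gweight)) {
    stats::setNames(meta$gweight, row_ids)
  } else {
    stats::setNames(rep(1, length(row_ids)), row_ids)
  }
  for (r in row_order) {
    cells <- ifelse(is.na(v[r, col_order]), "", sprintf("%.6g", v[r, col_order]))
    writeLines(paste(c(if (has_gid) gene_id[r], r, gname[r], sprintf("%.6g", gw[r]),
                       cells), collapse = "\t"), con, sep = "\n")
  }
  close(con)
  files <- c(cdt, files)
  invisible(files)
}
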