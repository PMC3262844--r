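#' Attribute (expression) matrix with explicit missingness
#'
#' Rows are nodes/genes, columns are arrays/conditions.  Missing cells are
#' `NA`.  Optional Cluster 3.0 metadata (gene names, GWEIGHT, EWEIGHT) rides
#' along but never participates in computation.
#'
#' @param values numeric matrix with unique rownames and colnames; `NA`
#'   marks missing cells.
#' @param name optional character vector of display names (one per row).
#' @param gweight,eweight optional numeric row/column weights (metadata only).
#' @return An object of class `attribute_matrix`.
#' @export
attribute_matrix <- function(values, name = NULL, gweight = NULL, eweight = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) stop_data("attribute matrix requires rownames")
  if (is.null(colnames(values))) colnames(values) <- paste0("V", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop_data("duplicate row ids: ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) stop_data("duplicate column ids")
  structure(list(values = values, name = name, gweight = gweight, eweight = eweight),
            class = "attribute_matrix")
}

#' @export
as.matrix.attribute_matrix <- function(x, ...) x$values

#' @export
print.attribute_matrix <- function(x, ...) {
  cat("attribute_matrix:", nrow(x$values), "rows x", ncol(x$values), "cols, ",
      sum(is.na(x$values)), "missing\n")
  invisible(x)
}

#' Row ids whose values are entirely missing
#'
#' Such rows are retained on ingest but excluded from clustering ("nodes
#' without data" semantics).
#' @param matrix an `attribute_matrix` or plain matrix
#' @return character vector of row ids
#' @export
rows_all_missing <- function(matrix) {
  v <- if (inherits(matrix, "attribute_matrix")) matrix$values else as.matrix(matrix)
  rownames(v)[rowSums(!is.na(v)) == 0L]
}

# Split one TSV line keeping trailing empty fields.
split_tsv <- function(line) {
  parts <- strsplit(paste0(line, "\x01"), "\t", fixed = TRUE)[[1]]
  n <- length(parts)
  parts[n] <- sub("\x01$", "", parts[n])
  parts
}

#' Read a tab-delimited expression matrix (plain or Cluster 3.0 / CDT dialect)
#'
#' The Cluster 3.0 family of formats has leading annotation columns (GID,
#' UNIQID / GENE-ID, NAME, GWEIGHT) and optional EWEIGHT / AID rows; the
#' plain dialect has a single leading id column.  Empty cells become missing
#' values.  Rows whose values are all missing are retained and flagged;
#' clustering functions drop them.
#'
#' @param path file path
#' @param dialect `"auto"` (default), `"plain"` or `"cluster"`
#' @return an [attribute_matrix()]
#' @export
read_matrix <- function(path, dialect = c("auto", "plain", "cluster")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_data("input file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) | seq_along(lines) < length(lines)]  # drop trailing blank
  if (length(lines) < 1L) stop_data("empty matrix file: ", path)
  rows <- lapply(lines, split_tsv)
  header <- rows[[1]]
  ncol_total <- length(header)

  ann_names <- c("GID", "UNIQID", "GENE-ID", "ORF", "NAME", "GWEIGHT")
  n_ann <- 0L
  while (n_ann < length(header) && toupper(header[n_ann + 1L]) %in% ann_names) {
    n_ann <- n_ann + 1L
  }
  if (dialect == "plain" || (dialect == "auto" && n_ann <= 1L)) n_ann <- 1L
  ann_cols <- toupper(header[seq_len(n_ann)])
  id_col <- which(ann_cols %in% c("UNIQID", "GENE-ID", "ORF"))[1]
  if (is.na(id_col)) id_col <- if (n_ann > 1L && ann_cols[1] == "GID") 2L else 1L
  name_col <- which(ann_cols == "NAME")[1]
  gweight_col <- which(ann_cols == "GWEIGHT")[1]
  col_ids <- header[-seq_len(n_ann)]

  body <- rows[-1]
  line_no <- seq_along(body) + 1L
  special <- vapply(body, function(r) toupper(r[1]) %in% c("EWEIGHT", "AID"), logical(1))
  eweight <- NULL; aid <- NULL
  for (r in body[special]) {
    vals <- r[-seq_len(min(n_ann, length(r)))]
    if (toupper(r[1]) == "EWEIGHT") eweight <- suppressWarnings(as.numeric(vals))
    if (toupper(r[1]) == "AID") aid <- vals
  }
  data_rows <- body[!special]
  data_line_no <- line_no[!special]
  if (length(data_rows) == 0L) stop_data("no data rows in ", path)

  lens <- lengths(data_rows)
  if (any(lens != ncol_total)) {
    bad <- data_line_no[lens != ncol_total][1]
    stop_data("ragged row at line ", bad, " (expected ", ncol_total, " fields)")
  }

  row_ids <- vapply(data_rows, `[`, character(1), id_col)
  if (anyDuplicated(row_ids)) {
    dup <- unique(row_ids[duplicated(row_ids)])
    stop_data("duplicate row ids: ", paste(dup, collapse = ", "))
  }
  name <- if (!is.na(name_col)) vapply(data_rows, `[`, character(1), name_col) else NULL
  gweight <- if (!is.na(gweight_col)) {
    suppressWarnings(as.numeric(vapply(data_rows, `[`, character(1), gweight_col)))
  } else NULL

  vals <- matrix(NA_real_, nrow = length(data_rows), ncol = length(col_ids),
                 dimnames = list(row_ids, col_ids))
  for (i in seq_along(data_rows)) {
    cells <- data_rows[[i]][-seq_len(n_ann)]
    empty <- cells == "" | toupper(cells) == "NA"
    num <- suppressWarnings(as.numeric(cells))
    bad <- !empty & is.na(num)
    if (any(bad)) {
      stop_data("non-numeric value '", cells[which(bad)[1]], "' at line ",
                data_line_no[i], ", column ", col_ids[which(bad)[1]])
    }
    vals[i, ] <- num
  }

  out <- attribute_matrix(vals, name = name, gweight = gweight, eweight = eweight)
  flagged <- rows_all_missing(out)
  if (length(flagged) > 0L) {
    ck_message(length(flagged), " row(s) have no data and will be ignored by clustering")
    attr(out, "flagged_rows") <- flagged
  }
  out
}

#' Write an attribute matrix as plain tab-delimited text
#'
#' One leading id column; missing values become empty cells.  Values are
#' written with up to 15 significant digits so a read/write round trip is
#' value-identical for ordinary data.
#' @param matrix an `attribute_matrix` or numeric matrix with rownames
#' @param path output path
#' @export
write_matrix <- function(matrix, path) {
  v <- if (inherits(matrix, "attribute_matrix")) matrix$values else as.matrix(matrix)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("ID", colnames(v)), collapse = "\t"), con, sep = "\n")
  for (i in seq_len(nrow(v))) {
    cells <- ifelse(is.na(v[i, ]), "", sprintf("%.15g", v[i, ]))
    writeLines(paste(c(rownames(v)[i], cells), collapse = "\t"), con, sep = "\n")
  }
  invisible(path)
}
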