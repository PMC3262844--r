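#' Read a weighted edge list (TSV or SIF)
#'
#' TSV files need header columns `source` and `target`; any numeric column
#' can serve as the weight.  SIF files (`node<TAB>interaction<TAB>node ...`,
#' detected by the `.sif` extension) get unit weights.  Directed input is
#' symmetrized: duplicate unordered pairs collapse to one edge keeping the
#' maximum weight (reported via a message).  When no weight column is named
#' or present, every edge gets weight 1.
#'
#' @param path edge file
#' @param weight_column name of the weight column; `NULL` uses a column
#'   named `weight` when present, unit weights otherwise.
#' @param nodes_path optional file with one node id per line (adds isolated
#'   nodes).
#' @param directed_policy how opposing directed duplicates are merged; only
#'   `"max"` is provided.
#' @return a [weighted_network()]
#' @export
read_edge_list <- function(path, weight_column = NULL, nodes_path = NULL,
                           directed_policy = "max") {
  directed_policy <- match.arg(directed_policy, "max")
  if (!file.exists(path)) stop_data("input file not found: ", path)
  extra_nodes <- character()
  if (!is.null(nodes_path)) {
    if (!file.exists(nodes_path)) stop_data("node file not found: ", nodes_path)
    extra_nodes <- readLines(nodes_path)
    extra_nodes <- extra_nodes[nzchar(extra_nodes)]
  }

  if (grepl("\\.sif$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    src <- character(); tgt <- character()
    for (ln in lines) {
      f <- strsplit(trimws(ln), "[\t ]+")[[1]]
      if (length(f) == 1L) {
        extra_nodes <- c(extra_nodes, f[1])
      } else if (length(f) >= 3L) {
        src <- c(src, rep(f[1], length(f) - 2L))
        tgt <- c(tgt, f[-(1:2)])
      } else {
        stop_data("malformed SIF line: ", ln)
      }
    }
    edges <- data.frame(source = src, target = tgt, weight = 1.0,
                        stringsAsFactors = FALSE)
    return(weighted_network(edges, nodes = extra_nodes))
  }

  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(weighted_network(NULL, nodes = extra_nodes))
  }
  header <- split_tsv(lines[1])
  if (!all(c("source", "target") %in% header)) {
    stop_data("edge list must have 'source' and 'target' header columns")
  }
  si <- match("source", header); ti <- match("target", header)
  wi <- NA_integer_
  if (!is.null(weight_column)) {
    wi <- match(weight_column, header)
    if (is.na(wi)) stop_data("weight column '", weight_column, "' not found")
  } else if ("weight" %in% header) {
    wi <- match("weight", header)
  }

  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(weighted_network(NULL, nodes = extra_nodes))
  }
  rows <- lapply(body, split_tsv)
  lens <- lengths(rows)
  if (any(lens < max(si, ti, wi, na.rm = TRUE))) {
    bad <- which(lens < max(si, ti, wi, na.rm = TRUE))[1]
    stop_data("ragged row at line ", bad + 1L)
  }
  src <- vapply(rows, `[`, character(1), si)
  tgt <- vapply(rows, `[`, character(1), ti)
  if (!is.na(wi)) {
    wraw <- vapply(rows, `[`, character(1), wi)
    w <- suppressWarnings(as.numeric(wraw))
    if (anyNA(w)) {
      bad <- which(is.na(w))[1]
      stop_data("non-numeric weight '", wraw[bad], "' at line ", bad + 1L)
    }
  } else {
    w <- rep(1.0, length(src))
  }
  weighted_network(data.frame(source = src, target = tgt, weight = w,
                              stringsAsFactors = FALSE),
                   nodes = extra_nodes)
}

#' Write a network as an edge-list TSV
#'
#' Weights are written with 17 significant digits, so reading the file back
#' reproduces the network exactly (ingest idempotence).  An `edge_type`
#' column (from [build_cluster_network()]) is preserved when present.
#' @param network a `weighted_network`
#' @param path output path
#' @export
write_edge_list <- function(network, path) {
  ed <- network$edges
  has_type <- "edge_type" %in% names(ed)
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c("source", "target", "weight", if (has_type) "edge_type")
  writeLines(paste(hdr, collapse = "\t"), con, sep = "\n")
  for (i in seq_len(nrow(ed))) {
    cells <- c(ed$source[i], ed$target[i], sprintf("%.17g", ed$weight[i]),
               if (has_type) ed$edge_type[i])
    writeLines(paste(cells, collapse = "\t"), con, sep = "\n")
  }
  invisible(path)
}
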