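#' Cluster assignment
#'
#' A partition (or, for MCODE with fluff, an overlapping cover) of node ids
#' into clusters.  Clusters are always stored size-descending with ties
#' broken by the lexicographically smallest member, and members are sorted
#' within each cluster, so the object is a deterministic function of the
#' partition regardless of how it was produced.
#'
#' @param clusters list of character vectors of node ids.
#' @param unassigned character vector of ids in no cluster (MCODE only for
#'   the built-in algorithms).
#' @param allow_overlap permit a node in more than one cluster (fluff).
#' @return object of class `cluster_assignment` with elements `clusters`,
#'   `unassigned` and `labels` (named integer vector; for overlapping covers
#'   the label is the first containing cluster).
#' @export
cluster_assignment <- function(clusters, unassigned = character(), allow_overlap = FALSE) {
  clusters <- lapply(clusters, function(m) lex_sort(unique(as.character(m))))
  clusters <- clusters[lengths(clusters) > 0L]
  if (length(clusters) > 0L) {
    sizes <- lengths(clusters)
    firsts <- vapply(clusters, `[`, character(1), 1L)
    clusters <- clusters[lex_order(-sizes, firsts)]
  }
  all_members <- unlist(clusters, use.names = FALSE)
  if (!allow_overlap && anyDuplicated(all_members)) {
    dup <- unique(all_members[duplicated(all_members)])
    stop_data("node(s) in more than one cluster: ", paste(dup, collapse = ", "))
  }
  unassigned <- lex_sort(unique(as.character(unassigned)))
  if (any(unassigned %in% all_members)) {
    stop_data("unassigned nodes overlap cluster members")
  }
  labels <- integer(0)
  if (length(clusters) > 0L) {
    labels <- rep(seq_along(clusters), lengths(clusters))
    names(labels) <- all_members
    labels <- labels[!duplicated(names(labels))]
    labels <- labels[lex_order(names(labels))]
  }
  structure(list(clusters = clusters, unassigned = unassigned, labels = labels),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment:", length(x$clusters), "clusters")
  if (length(x$unassigned)) cat(",", length(x$unassigned), "unassigned")
  cat("\n")
  if (length(x$clusters)) {
    cat("  sizes:", paste(utils::head(lengths(x$clusters), 10), collapse = " "),
        if (length(x$clusters) > 10) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.cluster_assignment <- function(x, ...) {
  rows <- data.frame(node = character(), cluster = integer(), stringsAsFactors = FALSE)
  if (length(x$clusters)) {
    rows <- data.frame(node = unlist(x$clusters, use.names = FALSE),
                       cluster = rep(seq_along(x$clusters), lengths(x$clusters)),
                       stringsAsFactors = FALSE)
  }
  if (length(x$unassigned)) {
    rows <- rbind(rows, data.frame(node = x$unassigned, cluster = NA_integer_,
                                   stringsAsFactors = FALSE))
  }
  rows
}

#' Number of clusters / cluster sizes
#' @param assignment a `cluster_assignment`
#' @export
n_clusters <- function(assignment) length(assignment$clusters)

#' @rdname n_clusters
#' @export
cluster_sizes <- function(assignment) lengths(assignment$clusters)

# labels as an integer vector aligned with a given id order (NA = unassigned)
labels_for <- function(assignment, ids) {
  lab <- assignment$labels[ids]
  names(lab) <- ids
  lab
}

# build an assignment from an integer/character label vector named by node id
assignment_from_labels <- function(labels) {
  ids <- names(labels)
  keep <- !is.na(labels)
  cl <- split(ids[keep], labels[keep])
  cluster_assignment(unname(cl), unassigned = ids[!keep])
}

#' Write / read a cluster assignment as TSV
#'
#' Two columns `node`, `cluster` (1-based, size-ordered); unassigned nodes
#' get an empty cluster field.  `read_assignment` restores an identical
#' partition.
#' @param assignment a `cluster_assignment`
#' @param path file path
#' @export
write_assignment <- function(assignment, path) {
  df <- as.data.frame(assignment)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("node\tcluster", con, sep = "\n")
  for (i in seq_len(nrow(df))) {
    cl <- if (is.na(df$cluster[i])) "" else as.character(df$cluster[i])
    writeLines(paste(df$node[i], cl, sep = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' @rdname write_assignment
#' @export
read_assignment <- function(path) {
  if (!file.exists(path)) stop_data("input file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 1L || split_tsv(lines[1])[1] != "node") {
    stop_data("not an assignment file (missing 'node' header): ", path)
  }
  body <- lapply(lines[-1], split_tsv)
  body <- body[lengths(body) >= 1 & vapply(body, function(r) nzchar(r[1]), logical(1))]
  nodes <- vapply(body, `[`, character(1), 1L)
  cl <- vapply(body, function(r) if (length(r) < 2L || r[2] == "") NA_character_ else r[2],
               character(1))
  labels <- as.integer(cl)
  names(labels) <- nodes
  assignment_from_labels(labels)
}
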