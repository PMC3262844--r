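# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Locale-independent lexicographic ordering: all deterministic tie-breaking
# in the package goes through these (radix sort uses the C locale).
lex_sort <- function(x) sort(x, method = "radix")
lex_order <- function(...) order(..., method = "radix")

# Canonical key for an unordered node pair.
pair_key <- function(a, b) {
  swap <- a > b
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  paste(lo, hi, sep = "\r")
}

ck_message <- function(...) {
  if (isTRUE(getOption("clustkit.verbose", TRUE))) message(...)
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("clustkit_data_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("clustkit_config_error", "error")))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)

# Simple union-find used by MCL attractor merging and tree cutting.
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

uf_labels <- function(parent) {
  roots <- vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
  match(roots, unique(roots))
}
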