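# Independent oracles and small builders used across the test files.
# Everything here is deliberately naive (double loops, exhaustive
# enumeration) and separate from the package's own code paths.

options(clustkit.verbose = FALSE)

# --- small graph builders ---------------------------------------------------

edge_df <- function(src, tgt, w = 1) {
  data.frame(source = src, target = tgt, weight = w, stringsAsFactors = FALSE)
}

clique_edges <- function(ids, w = 1) {
  cmb <- t(utils::combn(ids, 2))
  edge_df(cmb[, 1], cmb[, 2], w)
}

# two triangles {a,b,c}, {d,e,f} joined by bridge c-d
two_triangles_bridge <- function() {
  weighted_network(rbind(clique_edges(c("a", "b", "c")),
                         clique_edges(c("d", "e", "f")),
                         edge_df("c", "d")))
}

# --- adjusted Rand index (mclust as the oracle implementation) --------------

ari <- function(assignment, truth) {
  lab <- assignment$labels[names(truth)]
  lab[is.na(lab)] <- seq_len(sum(is.na(lab))) + max(assignment$labels, 0)
  mclust::adjustedRandIndex(as.integer(lab), as.integer(truth))
}

# --- naive O(n^3) agglomerative oracle --------------------------------------
# Works directly on cluster member lists, recomputing every linkage distance
# from the full pairwise distance matrix (or raw matrix for centroid) at
# every step; shares no code with cluster_hierarchical().

oracle_hclust <- function(D, linkage, X = NULL, metric = NULL) {
  ids <- rownames(D)
  clusters <- lapply(ids, identity)
  heights <- numeric(0)
  merged <- list()
  centroid_dist <- function(a, b) {
    ca <- colMeans(X[a, , drop = FALSE], na.rm = TRUE)
    cb <- colMeans(X[b, , drop = FALSE], na.rm = TRUE)
    oracle_pair_distance(ca, cb, metric, ncol(X))
  }
  link <- function(a, b) {
    if (linkage == "centroid") return(centroid_dist(a, b))
    dd <- as.vector(D[a, b, drop = FALSE])
    switch(linkage, single = min(dd), complete = max(dd), average = mean(dd))
  }
  while (length(clusters) > 1L) {
    best <- Inf; bi <- NA; bj <- NA
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        d <- link(clusters[[i]], clusters[[j]])
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])), method = "radix")
        if (d < best - 1e-300 ||
            (d == best && paste(key, collapse = "\r") <
               paste(sort(c(min(clusters[[bi]]), min(clusters[[bj]])),
                          method = "radix"), collapse = "\r"))) {
          best <- d; bi <- i; bj <- j
        }
      }
    }
    heights <- c(heights, best)
    merged[[length(merged) + 1L]] <-
      sort(c(paste(sort(clusters[[bi]], method = "radix"), collapse = ","),
             paste(sort(clusters[[bj]], method = "radix"), collapse = ",")),
           method = "radix")
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  list(heights = heights, merged = merged)
}

# canonical (child, child) description of each merge of an hclust object,
# comparable with oracle_hclust()$merged
hclust_merges <- function(tree) {
  n <- length(tree$labels)
  members <- vector("list", n - 1L)
  out <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    get <- function(code) if (code < 0) tree$labels[-code] else members[[code]]
    a <- get(tree$merge[s, 1]); b <- get(tree$merge[s, 2])
    members[[s]] <- c(a, b)
    out[[s]] <- sort(c(paste(sort(a, method = "radix"), collapse = ","),
                       paste(sort(b, method = "radix"), collapse = ",")),
                     method = "radix")
  }
  out
}

# --- naive pairwise distance oracle -----------------------------------------

oracle_pair_distance <- function(x, y, metric, p) {
  sh <- !is.na(x) & !is.na(y)
  xs <- x[sh]; ys <- y[sh]; m <- sum(sh)
  corr <- metric %in% c("pearson", "pearson_abs", "uncentered", "uncentered_abs",
                        "spearman", "kendall")
  if (corr) {
    if (m < 2) return(2)
    r <- switch(metric,
      pearson = , pearson_abs =
        if (sd(xs) == 0 || sd(ys) == 0) 0 else cor(xs, ys),
      uncentered = , uncentered_abs = {
        den <- sqrt(sum(xs^2) * sum(ys^2))
        if (den == 0) 0 else sum(xs * ys) / den
      },
      spearman = if (length(unique(xs)) < 2 || length(unique(ys)) < 2) 0
                 else cor(xs, ys, method = "spearman"),
      kendall = if (length(unique(xs)) < 2 || length(unique(ys)) < 2) 0
                else cor(xs, ys, method = "kendall"))
    if (is.na(r)) r <- 0
    d <- if (grepl("_abs$", metric)) 1 - abs(r) else 1 - r
    return(min(max(d, 0), 2))
  }
  if (metric == "euclidean") sqrt(sum((xs - ys)^2) * p / m)
  else sum(abs(xs - ys)) * p / m
}

oracle_distance_matrix <- function(X, metric) {
  n <- nrow(X)
  D <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) D[i, j] <- oracle_pair_distance(X[i, ], X[j, ], metric, ncol(X))
    }
  }
  # pairs with no shared observations under a non-correlation metric take
  # the largest finite distance (the documented substitution)
  if (any(!is.finite(D))) {
    mx <- suppressWarnings(max(D[is.finite(D)]))
    if (!is.finite(mx)) mx <- 0
    D[!is.finite(D)] <- mx
  }
  D
}

# --- exhaustive set-partition enumeration -----------------------------------

all_partitions <- function(n) {
  out <- list()
  labels <- integer(n)
  recurse <- function(i, maxlab) {
    if (i > n) { out[[length(out) + 1L]] <<- labels; return(invisible()) }
    for (l in seq_len(maxlab + 1L)) {
      labels[i] <<- l
      recurse(i + 1L, max(maxlab, l))
    }
  }
  recurse(1L, 0L)
  out
}

oracle_editing_cost <- function(s, lab, threshold) {
  n <- nrow(s); cost <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    same <- lab[i] == lab[j]
    if (same && s[i, j] < threshold) cost <- cost + threshold - s[i, j]
    if (!same && s[i, j] > threshold) cost <- cost + s[i, j] - threshold
  }
  cost
}

oracle_modularity <- function(net, lab) {
  ed <- net$edges
  m <- nrow(ed)
  if (m == 0) return(0)
  deg <- table(factor(c(ed$source, ed$target), levels = net$nodes))
  q <- 0
  for (c in unique(lab)) {
    mem <- names(lab)[lab == c]
    e_c <- sum(ed$source %in% mem & ed$target %in% mem)
    q <- q + e_c / m - (sum(deg[mem]) / (2 * m))^2
  }
  q
}
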