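#' Agglomerative hierarchical clustering (Cluster 3.0 semantics)
#'
#' Classic bottom-up agglomeration: at every step the pair of current
#' clusters at minimal linkage distance is merged and the merge height
#' recorded.  Ties are broken deterministically by the lexicographically
#' smallest pair of smallest member ids.  Linkages:
#' \describe{
#'   \item{single / complete}{minimum / maximum pairwise distance}
#'   \item{average}{unweighted mean over all cross pairs (UPGMA)}
#'   \item{centroid}{the centroid of each cluster is recomputed as the
#'     per-column mean of its members (missing values ignored) and the
#'     distance between centroids is re-evaluated in the distance metric;
#'     requires `matrix`.  Centroid linkage can produce height inversions,
#'     which are reported and rendered as-is.}
#' }
#' The leaf ordering places, at every internal node, the child containing
#' the lexicographically smallest leaf on the left.
#'
#' @param distance a [compute_distance()] result
#' @param linkage `"average"` (default), `"single"`, `"complete"`, `"centroid"`
#' @param matrix the raw data matrix (rows matching `distance$ids`);
#'   required for centroid linkage
#' @return an object of class `hclust` (merge matrix, heights, leaf order,
#'   labels), directly usable with [cut_tree()], [write_treeview()] and
#'   base-R dendrogram tools
#' @export
cluster_hierarchical <- function(distance, linkage = c("average", "single",
                                                       "complete", "centroid"),
                                 matrix = NULL) {
  linkage <- match.arg(linkage)
  ids <- distance$ids
  n <- length(ids)
  if (n < 2L) stop_data("hierarchical clustering needs at least 2 items")
  D <- distance$d
  if (linkage == "centroid") {
    if (is.null(matrix)) stop_config("centroid linkage requires the raw matrix")
    v <- if (inherits(matrix, "attribute_matrix")) matrix$values else as.matrix(matrix)
    v <- v[ids, , drop = FALSE]
  }

  # active cluster bookkeeping ------------------------------------------------
  members <- as.list(seq_len(n))           # row indices per active cluster
  min_id <- ids                            # smallest member id per cluster
  node <- as.integer(-seq_len(n))          # hclust code: -leaf or +merge index
  active <- rep(TRUE, n + 0L)
  Dcur <- D                                # current cluster-to-cluster distances
  diag(Dcur) <- Inf
  if (linkage == "centroid") {
    cent <- v
    p <- ncol(v)
  }

  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  children <- vector("list", n - 1L)

  for (step in seq_len(n - 1L)) {
    act <- which(active)
    sub <- Dcur[act, act, drop = FALSE]
    m <- min(sub)
    cand <- which(sub == m, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # tie-break: lexicographically smallest sorted pair of smallest member ids
    keys1 <- character(nrow(cand)); keys2 <- character(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      a <- min_id[act[cand[r, 1]]]; b <- min_id[act[cand[r, 2]]]
      keys1[r] <- min(a, b); keys2[r] <- max(a, b)
    }
    pick <- lex_order(keys1, keys2)[1]
    ci <- act[cand[pick, 1]]; cj <- act[cand[pick, 2]]

    merge[step, ] <- sort(c(node[ci], node[cj]))
    height[step] <- m
    children[[step]] <- c(node[ci], node[cj])

    new_members <- c(members[[ci]], members[[cj]])
    ni <- length(members[[ci]]); nj <- length(members[[cj]])

    # distances from the merged cluster to every other active cluster
    others <- setdiff(act, c(ci, cj))
    if (linkage == "centroid") {
      cnew <- colMeans(v[new_members, , drop = FALSE], na.rm = TRUE)
      cnew[is.nan(cnew)] <- NA_real_
      cent[ci, ] <- cnew
    }
    for (ck in others) {
      dnew <- switch(linkage,
        single   = min(Dcur[ci, ck], Dcur[cj, ck]),
        complete = max(Dcur[ci, ck], Dcur[cj, ck]),
        average  = (ni * Dcur[ci, ck] + nj * Dcur[cj, ck]) / (ni + nj),
        centroid = {
          co <- if (length(members[[ck]]) == 1L) v[members[[ck]], ] else
            colMeans(v[members[[ck]], , drop = FALSE], na.rm = TRUE)
          d <- pair_distance(cent[ci, ], co, distance$metric, p_total = p)
          if (is.na(d)) { if (distance$metric %in% CORRELATION_METRICS) 2 else 0 } else d
        })
      Dcur[ci, ck] <- dnew
      Dcur[ck, ci] <- dnew
    }
    members[[ci]] <- new_members
    min_id[ci] <- min(min_id[ci], min_id[cj])
    node[ci] <- step
    active[cj] <- FALSE
    Dcur[cj, ] <- Inf
    Dcur[, cj] <- Inf
  }

  if (any(diff(height) < -1e-12)) {
    ck_message("centroid-linkage inversion(s) present: merge heights are not monotone")
  }

  # leaf order: child containing the lexicographically smallest leaf goes left
  smallest_leaf <- function(code) {
    if (code < 0) ids[-code] else tree_min[code]
  }
  tree_min <- character(n - 1L)
  for (step in seq_len(n - 1L)) {
    tree_min[step] <- min(smallest_leaf(children[[step]][1]),
                          smallest_leaf(children[[step]][2]))
  }
  leaves_of <- function(code) {
    if (code < 0) return(-code)
    ch <- children[[code]]
    left_first <- smallest_leaf(ch[1]) <= smallest_leaf(ch[2])
    if (left_first) c(leaves_of(ch[1]), leaves_of(ch[2]))
    else c(leaves_of(ch[2]), leaves_of(ch[1]))
  }
  ord <- leaves_of(n - 1L)

  structure(list(merge = merge, height = height, order = ord, labels = ids,
                 method = linkage, dist.method = distance$metric,
                 call = match.call()),
            class = "hclust")
}

#' Cut a dendrogram into groups
#'
#' Either at a height (`h`): merges are applied in increasing height order
#' and those above `h` are discarded; or into `k` groups: the `n - k`
#' lowest merges are applied.  With distinct heights the `k`-group cut is
#' the unique level with that group count.
#'
#' @param tree an `hclust` object (e.g. from [cluster_hierarchical()])
#' @param h height threshold (merges with height <= h are kept)
#' @param k desired number of groups
#' @return a [cluster_assignment()]
#' @export
cut_tree <- function(tree, h = NULL, k = NULL) {
  if (is.null(h) == is.null(k)) stop_config("supply exactly one of h or k")
  n <- length(tree$labels)
  n_merge <- n - 1L
  if (!is.null(k)) {
    if (!is_count(k) || k > n) stop_config("k must be an integer in [1, ", n, "]")
    keep_idx <- order(tree$height)[seq_len(n - as.integer(k))]
    apply_merge <- seq_len(n_merge) %in% keep_idx
  } else {
    apply_merge <- tree$height <= h
  }
  # a leaf inside each merge's subtree (children precede parents in merge order)
  rep_of <- integer(n_merge)
  for (s in seq_len(n_merge)) {
    ch1 <- tree$merge[s, 1]
    rep_of[s] <- if (ch1 < 0) -ch1 else rep_of[ch1]
  }
  parent <- uf_new(n)
  for (s in seq_len(n_merge)) {
    if (!apply_merge[s]) next
    ch <- tree$merge[s, ]
    li <- if (ch[1] < 0) -ch[1] else rep_of[ch[1]]
    lj <- if (ch[2] < 0) -ch[2] else rep_of[ch[2]]
    parent <- uf_union(parent, li, lj)
  }
  lab <- uf_labels(parent)
  assignment_from_labels(stats::setNames(lab, tree$labels))
}
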