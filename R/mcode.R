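#' MCODE molecular complex detection
#'
#' Three-stage detection of dense complexes in an interaction network
#' (weights are ignored; the topology alone matters).  Stage 1 weights each
#' vertex by the product of the highest k-core number of its closed
#' neighborhood and the density of that core (the core clustering
#' coefficient).  Stage 2 grows a complex from the highest-weight unseen
#' vertex, admitting neighbors whose weight is at least
#' `(1 - vertex_weight_percentage)` times the seed weight, breadth-first to
#' `max_depth`; a vertex joins at most one complex at this stage.  Stage 3
#' optionally fluffs each complex (adds outside neighbors whose closed
#' neighborhood density exceeds `fluff_density_cutoff`; may create overlap),
#' then optionally applies the haircut (removes nodes with fewer than two
#' connections inside the complex), and finally discards complexes that do
#' not contain a `k_core`-core.  Complexes are scored by density times
#' size; the returned assignment follows the global size-ordering
#' convention and lists untouched nodes as unassigned.
#'
#' @param network a `weighted_network`
#' @param vertex_weight_percentage expansion tolerance in (0, 1]
#' @param haircut remove singly-connected members (default TRUE)
#' @param fluff add dense outside neighbors (default FALSE)
#' @param fluff_density_cutoff density threshold for fluff in \[0, 1\]
#' @param k_core minimum core a complex must contain (>= 2)
#' @param max_depth breadth-first expansion depth limit
#' @return a [cluster_assignment()] (overlapping only when fluff is on);
#'   attribute `"scores"` gives density x size per returned cluster
#' @export
cluster_mcode <- function(network, vertex_weight_percentage = 0.2, haircut = TRUE,
                          fluff = FALSE, fluff_density_cutoff = 0.5,
                          k_core = 2, max_depth = 100) {
  if (vertex_weight_percentage <= 0 || vertex_weight_percentage > 1) {
    stop_config("vertex_weight_percentage must be in (0, 1]")
  }
  if (fluff_density_cutoff < 0 || fluff_density_cutoff > 1) {
    stop_config("fluff_density_cutoff must be in [0, 1]")
  }
  if (k_core < 2) stop_config("k_core must be >= 2")
  ids <- network$nodes
  if (length(ids) == 0L || n_edges(network) == 0L) {
    return(cluster_assignment(list(), unassigned = ids))
  }
  if (n_edges(network) > 0L) ck_message("MCODE ignores edge weights")
  g <- as_igraph(network, weighted = FALSE)
  adj <- adjacency_list(network)

  subgraph_density <- function(vids) {
    if (length(vids) < 2L) return(0)
    sub <- igraph::induced_subgraph(g, vids)
    2 * igraph::ecount(sub) / (length(vids) * (length(vids) - 1))
  }

  # stage 1: vertex weighting
  vweight <- stats::setNames(numeric(length(ids)), ids)
  for (v in ids) {
    nb <- c(v, adj[[v]])
    if (length(nb) < 2L) { vweight[v] <- 0; next }
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    core_vs <- igraph::V(sub)$name[core >= kmax]
    vweight[v] <- kmax * subgraph_density(core_vs)
  }

  # stage 2: seeded greedy expansion
  order_ids <- ids[lex_order(-vweight, ids)]
  seen <- stats::setNames(rep(FALSE, length(ids)), ids)
  complexes <- list()
  for (seed in order_ids) {
    if (seen[seed]) next
    threshold <- vweight[seed] * (1 - vertex_weight_percentage)
    members <- seed
    seen[seed] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) > 0L && depth < max_depth) {
      nxt <- character()
      for (u in frontier) {
        for (w in adj[[u]]) {
          if (!seen[w] && vweight[w] >= threshold) {
            seen[w] <- TRUE
            members <- c(members, w)
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    complexes[[length(complexes) + 1L]] <- members
  }

  # stage 3: post-processing
  out <- list()
  scores <- numeric()
  for (members in complexes) {
    if (fluff) {
      extra <- character()
      for (u in members) {
        for (w in setdiff(adj[[u]], c(members, extra))) {
          if (subgraph_density(c(w, adj[[w]])) > fluff_density_cutoff) {
            extra <- c(extra, w)
          }
        }
      }
      members <- c(members, extra)
    }
    if (haircut && length(members) > 1L) {
      sub <- igraph::induced_subgraph(g, members)
      deg <- igraph::degree(sub)
      members <- igraph::V(sub)$name[deg >= 2]
    }
    if (length(members) < 2L) next
    sub <- igraph::induced_subgraph(g, members)
    if (max(igraph::coreness(sub)) < k_core) next
    out[[length(out) + 1L]] <- members
    scores <- c(scores, subgraph_density(members) * length(members))
  }

  assigned <- unique(unlist(out, use.names = FALSE))
  res <- cluster_assignment(out, unassigned = setdiff(ids, assigned),
                            allow_overlap = fluff)
  # report scores in the returned (size-ordered) cluster order
  if (length(out) > 0L) {
    key <- vapply(res$clusters, paste, character(1), collapse = "\r")
    orig_key <- vapply(lapply(out, lex_sort), paste, character(1), collapse = "\r")
    attr(res, "scores") <- scores[match(key, orig_key)]
  }
  res
}
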