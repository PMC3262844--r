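# -- MCL ----------------------------------------------------------------------

test_that("MCL keeps flow inside connected components and handles singletons", {
  two_tri <- weighted_network(rbind(clique_edges(c("a", "b", "c")),
                                    clique_edges(c("x", "y", "z"))))
  res <- cluster_mcl(two_tri, inflation = 2)
  expect_equal(cluster_sizes(res), c(3L, 3L))
  expect_identical(res$clusters[[1]], c("a", "b", "c"))

  single <- weighted_network(NULL, nodes = "solo")
  expect_equal(cluster_sizes(cluster_mcl(single)), 1L)

  expect_error(cluster_mcl(weighted_network(edge_df("a", "b", -1))), "negative")
})

test_that("MCL separates two 5-cliques joined by a weak bridge", {
  ids_a <- paste0("a", 1:5); ids_b <- paste0("b", 1:5)
  net <- weighted_network(rbind(clique_edges(ids_a), clique_edges(ids_b),
                                edge_df("a1", "b1", 0.1)))
  res <- cluster_mcl(net, inflation = 2, max_iterations = 100)
  expect_equal(cluster_sizes(res), c(5L, 5L))
  expect_identical(res$clusters[[1]], ids_a)
  expect_identical(res$clusters[[2]], ids_b)
})

test_that("MCL iterates stay column-stochastic and the partition covers all nodes", {
  pp <- planted_partition(c(8, 8, 8), 0.6, 0.05, seed = 17)
  res <- cluster_mcl(pp$network, inflation = 2, max_iterations = 60)
  d <- attr(res, "diagnostics")
  expect_true(all(d$max_col_dev < 1e-9))
  covered <- unlist(res$clusters)
  expect_identical(sort(covered, method = "radix"), pp$network$nodes)
  expect_length(res$unassigned, 0)
  # clusters never span components: check on a disconnected graph
  two <- weighted_network(rbind(clique_edges(c("a", "b", "c")),
                                clique_edges(c("p", "q", "r"))))
  cc <- cluster_connected_components(two)$labels
  mcl <- cluster_mcl(two)$labels
  for (cl in split(names(mcl), mcl)) {
    expect_length(unique(cc[cl]), 1L)
  }
})

# -- affinity propagation -----------------------------------------------------

test_that("affinity propagation recovers two blobs, matching the exhaustive exemplar oracle", {
  ids <- paste0("p", 1:6)
  truth <- setNames(c(1, 1, 1, 2, 2, 2), ids)
  S <- ifelse(outer(truth, truth, "=="), -0.1, -10)
  set.seed(7)
  J <- matrix(rnorm(36, sd = 1e-4), 6, 6); J <- (J + t(J)) / 2
  S <- S + J
  dimnames(S) <- list(ids, ids)
  pref <- median(S[row(S) != col(S)])

  # oracle: exhaustive search over exemplar subsets maximizing net similarity
  Sp <- S; diag(Sp) <- pref
  best <- -Inf; best_k <- NA
  for (k in 1:6) {
    for (ex in utils::combn(6, k, simplify = FALSE)) {
      val <- sum(diag(Sp)[ex]) +
        sum(apply(Sp[-ex, ex, drop = FALSE], 1, max))
      if (val > best) { best <- val; best_k <- length(ex) }
    }
  }
  expect_equal(best_k, 2L)

  res <- cluster_ap(S)
  expect_equal(n_clusters(res), 2L)
  expect_equal(ari(res, truth), 1.0)
  ex <- attr(res, "exemplars")
  expect_length(ex, 2L)
  expect_true(all(vapply(res$clusters, function(cl) any(ex %in% cl), logical(1))))
})

test_that("affinity propagation degenerate preferences behave as expected", {
  ids <- c("a", "b", "c")
  S <- matrix(-1, 3, 3, dimnames = list(ids, ids))
  res <- cluster_ap(S, preference = 100)   # dominates every similarity
  expect_equal(n_clusters(res), 3L)

  one <- matrix(0, 1, 1, dimnames = list("solo", "solo"))
  r1 <- cluster_ap(one)
  expect_identical(attr(r1, "exemplars"), "solo")

  expect_error(cluster_ap(matrix(0, 2, 3)), "square")
})

# -- MCODE --------------------------------------------------------------------

test_that("MCODE extracts a K4 and leaves the pendant unassigned", {
  k4 <- clique_edges(c("a", "b", "c", "d"))
  net <- suppressMessages(weighted_network(rbind(k4, edge_df("d", "e"))))
  res <- suppressMessages(cluster_mcode(net))
  expect_equal(n_clusters(res), 1L)
  expect_identical(res$clusters[[1]], c("a", "b", "c", "d"))
  expect_identical(res$unassigned, "e")
  expect_equal(attr(res, "scores"), 4)  # density 1 x size 4
})

test_that("MCODE on two K4s joined by a bridge follows the staged rules", {
  # all 8 vertices carry vertex weight 3 (3-core of the closed neighborhood,
  # density 1), so expansion at vwp 0.2 admits the far side of the bridge:
  # hand-executing the stages yields a single 8-node complex
  net <- weighted_network(rbind(clique_edges(paste0("a", 1:4)),
                                clique_edges(paste0("b", 1:4)),
                                edge_df("a1", "b1")))
  res <- suppressMessages(cluster_mcode(net, vertex_weight_percentage = 0.2))
  expect_equal(cluster_sizes(res), 8L)
  expect_length(res$unassigned, 0L)
})

test_that("MCODE trivia: edgeless graphs yield nothing; haircut trims pendants", {
  empty <- weighted_network(NULL, nodes = c("a", "b"))
  res <- cluster_mcode(empty)
  expect_equal(n_clusters(res), 0L)
  expect_identical(res$unassigned, c("a", "b"))

  # triangle with a pendant: haircut removes the pendant from the complex
  net <- suppressMessages(weighted_network(rbind(clique_edges(c("a", "b", "c")),
                                                 edge_df("c", "z"))))
  with_hc <- suppressMessages(cluster_mcode(net, haircut = TRUE,
                                            vertex_weight_percentage = 1))
  expect_false("z" %in% unlist(with_hc$clusters))
})

# -- Girvan-Newman ------------------------------------------------------------

test_that("Girvan-Newman finds the two triangles with Q = 5/14", {
  net <- two_triangles_bridge()
  res <- cluster_girvan_newman(net)
  expect_equal(attr(res, "Q"), 5 / 14)
  expect_identical(res$clusters, list(c("a", "b", "c"), c("d", "e", "f")))
  # the recorded-level maximum agrees with exhaustive search over all
  # partitions of the 6 nodes (GN levels cannot beat the global optimum here)
  labs <- all_partitions(6)
  best <- max(vapply(labs, function(l) {
    oracle_modularity(net, setNames(l, net$nodes))
  }, numeric(1)))
  expect_equal(attr(res, "Q"), best)
})

test_that("Girvan-Newman returns the max-Q level; single cliques stay whole", {
  k4 <- weighted_network(clique_edges(c("a", "b", "c", "d")))
  res <- cluster_girvan_newman(k4)
  expect_equal(n_clusters(res), 1L)
  expect_equal(attr(res, "Q"), 0)
  lv <- attr(res, "levels")
  expect_equal(attr(res, "Q"), max(lv$Q))

  # communities never span components
  disc <- weighted_network(rbind(clique_edges(c("a", "b", "c")),
                                 clique_edges(c("x", "y", "z"))))
  rd <- cluster_girvan_newman(disc)
  comp <- cluster_connected_components(disc)$labels
  for (cl in rd$clusters) expect_length(unique(comp[cl]), 1L)

  # edgeless graph: all singletons, Q = 0
  iso <- weighted_network(NULL, nodes = c("a", "b"))
  ri <- cluster_girvan_newman(iso)
  expect_equal(n_clusters(ri), 2L)
  expect_equal(attr(ri, "Q"), 0)
})

test_that("Girvan-Newman recorded Q values match the direct formula on random graphs", {
  for (seed in 1:3) {
    pp <- planted_partition(c(4, 4), 0.9, 0.3, seed = seed)
    res <- cluster_girvan_newman(pp$network)
    lv <- attr(res, "levels")
    expect_equal(attr(res, "Q"), max(lv$Q))
    expect_equal(attr(res, "Q"),
                 oracle_modularity(pp$network, res$labels))
  }
})

# -- connected components -----------------------------------------------------

test_that("connected components are invariant to relabeling and count correctly", {
  iso <- weighted_network(NULL, nodes = c("a", "b", "c"))
  expect_equal(cluster_sizes(cluster_connected_components(iso)), c(1L, 1L, 1L))

  path <- weighted_network(edge_df(c("a", "b", "c"), c("b", "c", "d")))
  expect_equal(n_clusters(cluster_connected_components(path)), 1L)

  relab <- weighted_network(edge_df(c("w", "x", "y"), c("x", "y", "z")))
  expect_equal(cluster_sizes(cluster_connected_components(relab)),
               cluster_sizes(cluster_connected_components(path)))
})

# -- transitivity clustering --------------------------------------------------

test_that("transclust exact mode matches exhaustive set-partition enumeration", {
  ids <- c("a", "b", "c")
  s <- matrix(c(0, 2, -1, 2, 0, 2, -1, 2, 0), 3, dimnames = list(ids, ids))
  res <- cluster_transclust(s, threshold = 0)
  # oracle: enumerate all 5 partitions of 3 elements
  costs <- vapply(all_partitions(3), function(l) oracle_editing_cost(s, l, 0),
                  numeric(1))
  expect_equal(attr(res, "cost"), min(costs))
  expect_equal(attr(res, "cost"), 1)
  expect_equal(n_clusters(res), 1L)

  set.seed(31)
  for (n in c(4, 6, 8)) {
    idn <- sprintf("v%d", seq_len(n))
    sm <- matrix(rnorm(n * n), n, n); sm <- (sm + t(sm)) / 2; diag(sm) <- 0
    dimnames(sm) <- list(idn, idn)
    res <- cluster_transclust(sm, threshold = 0.2, exact_limit = 8)
    costs <- vapply(all_partitions(n), function(l) oracle_editing_cost(sm, l, 0.2),
                    numeric(1))
    expect_equal(attr(res, "cost"), min(costs), tolerance = 1e-12)
    expect_true(attr(res, "exact"))
    # heuristic on the same instance never beats the exact optimum
    h <- cluster_transclust(sm, threshold = 0.2, exact_limit = 2)
    expect_false(attr(h, "exact"))
    expect_gte(attr(h, "cost") + 1e-12, min(costs))
  }
})

test_that("transclust trivia: transitive inputs cost 0; singletons work", {
  ids <- sprintf("v%d", 1:6)
  truth <- setNames(rep(1:2, each = 3), ids)
  s <- ifelse(outer(truth, truth, "=="), 10, -10)
  dimnames(s) <- list(ids, ids); diag(s) <- 0
  res <- cluster_transclust(s, threshold = 0)
  expect_equal(attr(res, "cost"), 0)
  expect_equal(n_clusters(res), 2L)

  one <- matrix(0, 1, 1, dimnames = list("a", "a"))
  r1 <- cluster_transclust(one, threshold = 0)
  expect_equal(cluster_sizes(r1), 1L)
  expect_equal(attr(r1, "cost"), 0)

  asym <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(cluster_transclust(asym, 0), "symmetric")
})

# -- SCPS ---------------------------------------------------------------------

test_that("SCPS eigengap selection recovers exact blocks and the all-equal case", {
  ids <- sprintf("q%d", 1:6)
  truth <- setNames(rep(1:2, each = 3), ids)
  s <- similarity_from_labels(truth, s_in = 1, s_out = 0)
  res <- cluster_scps(s)
  expect_equal(attr(res, "k"), 2L)
  expect_identical(res$clusters, list(c("q1", "q2", "q3"), c("q4", "q5", "q6")))
  # eigengap oracle: block-diagonal normalized similarity has eigenvalue 1
  # with multiplicity = number of blocks
  expect_equal(sum(attr(res, "eigenvalues") > 0.99), 2L)

  alleq <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(n_clusters(cluster_scps(alleq)), 1L)
})

test_that("SCPS is permutation-equivariant and splits zero-degree nodes off", {
  ids <- sprintf("q%d", 1:9)
  truth <- setNames(rep(1:3, each = 3), ids)
  s <- similarity_from_labels(truth, s_in = 1, s_out = 0.05, jitter_sd = 0.02,
                              seed = 5)
  res <- cluster_scps(s, seed = 2)
  set.seed(99)
  perm <- sample(9)
  sp <- s[perm, perm]
  resp <- cluster_scps(sp, seed = 2)
  expect_identical(res$clusters, resp$clusters)

  s0 <- s
  s0["q9", ] <- 0; s0[, "q9"] <- 0
  r0 <- cluster_scps(s0, seed = 2)
  expect_true(any(vapply(r0$clusters, identical, logical(1), "q9")))
})

# -- shared contracts ---------------------------------------------------------

test_that("every partition algorithm covers each node exactly once, deterministically", {
  pp <- planted_partition(c(6, 6), 0.8, 0.1, seed = 23)
  net <- pp$network
  A <- adjacency_from_edge_attribute(net)
  runs <- list(
    mcl = function() cluster_mcl(net, max_iterations = 50),
    gn = function() cluster_girvan_newman(net),
    cc = function() cluster_connected_components(net),
    ap = function() cluster_ap(A),
    transclust = function() cluster_transclust(A, threshold = 0.5),
    scps = function() cluster_scps(A, seed = 4)
  )
  for (nm in names(runs)) {
    r1 <- runs[[nm]]()
    r2 <- runs[[nm]]()
    members <- unlist(r1$clusters)
    expect_identical(sort(members, method = "radix"), net$nodes, label = nm)
    expect_length(r1$unassigned, 0)
    expect_identical(r1$clusters, r2$clusters, label = paste(nm, "determinism"))
  }
})
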