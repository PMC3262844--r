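# -- hierarchical -------------------------------------------------------------

test_that("single and complete linkage on {0, 1, 10} match the hand-built tree", {
  m <- matrix(c(0, 1, 10), 3, 1, dimnames = list(c("a", "b", "c"), "x"))
  d <- compute_distance(m, "euclidean")
  hs <- cluster_hierarchical(d, "single")
  expect_equal(hs$height, c(1, 9))
  hc <- cluster_hierarchical(d, "complete")
  expect_equal(hc$height, c(1, 10))
  expect_identical(hs$labels[hs$order][1], "a")  # smallest leaf placed left

  # identical rows merge at height 0
  m2 <- matrix(c(1, 2, 1, 2, 9, 9), 3, 2, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), NULL))
  h0 <- cluster_hierarchical(compute_distance(m2, "euclidean"), "average")
  expect_equal(h0$height[1], 0)

  expect_error(cluster_hierarchical(compute_distance(m[1, , drop = FALSE],
                                                     "euclidean"), "single"),
               "at least 2")
})

test_that("all four linkages agree with the naive O(n^3) agglomeration oracle", {
  set.seed(41)
  for (rep in 1:8) {
    X <- matrix(rnorm(24), 8, 3, dimnames = list(sprintf("r%d", 1:8), NULL))
    metric <- c("euclidean", "uncentered", "pearson", "cityblock")[(rep %% 4) + 1]
    d <- compute_distance(X, metric)
    for (linkage in c("single", "complete", "average", "centroid")) {
      tree <- cluster_hierarchical(d, linkage, matrix = X)
      want <- oracle_hclust(d$d, linkage, X = X, metric = metric)
      expect_equal(tree$height, want$heights, tolerance = 1e-10,
                   label = paste(metric, linkage, "heights"))
      expect_identical(hclust_merges(tree), want$merged,
                       label = paste(metric, linkage, "merges"))
    }
  }
})

test_that("single/complete/average merge heights never decrease", {
  set.seed(42)
  X <- matrix(rnorm(30), 10, 3, dimnames = list(sprintf("r%02d", 1:10), NULL))
  d <- compute_distance(X, "euclidean")
  for (linkage in c("single", "complete", "average")) {
    tree <- cluster_hierarchical(d, linkage)
    expect_true(all(diff(tree$height) >= -1e-12), label = linkage)
  }
})

test_that("cut_tree slices at heights and group counts", {
  m <- matrix(c(0, 1, 10), 3, 1, dimnames = list(c("a", "b", "c"), "x"))
  tree <- cluster_hierarchical(compute_distance(m, "euclidean"), "single")
  expect_equal(n_clusters(cut_tree(tree, h = 100)), 1L)
  expect_equal(n_clusters(cut_tree(tree, h = -1)), 3L)
  mid <- cut_tree(tree, h = 5)
  expect_identical(mid$clusters, list(c("a", "b"), "c"))
  expect_identical(cut_tree(tree, k = 2)$clusters, mid$clusters)
  expect_error(cut_tree(tree, k = 4), "\\[1, 3\\]")
  expect_error(cut_tree(tree), "exactly one")
})

# -- k-means / k-medoid -------------------------------------------------------

test_that("k-means recovers two blobs with the exhaustively optimal objective", {
  mb <- matrix(c(0, 0.1, 10, 10.1), 4, 1, dimnames = list(paste0("r", 1:4), "x"))
  # oracle: all 7 two-partitions of 4 points, objective = sum of euclidean
  # distances to the cluster centroid
  obj <- function(lab) {
    sum(vapply(unique(lab), function(c) {
      v <- mb[lab == c, 1]; sum(abs(v - mean(v)))
    }, numeric(1)))
  }
  parts <- Filter(function(l) length(unique(l)) == 2, all_partitions(4))
  oracle_best <- min(vapply(parts, obj, numeric(1)))
  expect_equal(oracle_best, 0.2)

  km <- cluster_kmeans(mb, 2, seed = 1)
  expect_identical(km$clusters, list(c("r1", "r2"), c("r3", "r4")))
  expect_equal(attr(km, "wcss"), oracle_best)

  # k = n: every row its own cluster, objective 0
  kn <- cluster_kmeans(mb, 4, seed = 1)
  expect_equal(cluster_sizes(kn), rep(1L, 4))
  expect_equal(attr(kn, "wcss"), 0)

  # determinism under a fixed seed
  expect_identical(cluster_kmeans(mb, 2, seed = 7)$clusters,
                   cluster_kmeans(mb, 2, seed = 7)$clusters)
  expect_error(cluster_kmeans(mb, 9), "exceeds")
})

test_that("the euclidean Lloyd energy is non-increasing across iterations", {
  # the mean-update step minimizes the within-cluster sum of squared
  # distances, so that energy is the monotone quantity; the plain distance
  # sum (reported as wcss) can tick up transiently and is not asserted
  set.seed(5)
  for (s in 1:4) {
    X <- matrix(rnorm(60), 20, 3, dimnames = list(sprintf("r%02d", 1:20), NULL))
    km <- cluster_kmeans(X, 3, n_init = 2, seed = s)
    h <- attr(km, "history_sq")
    expect_true(all(diff(h) <= 1e-9), label = paste("seed", s))
  }
})

test_that("k-means drops all-missing rows into the unassigned set", {
  X <- matrix(c(0, 0.1, 10, NA), 4, 1, dimnames = list(paste0("r", 1:4), "x"))
  X[4, ] <- NA
  km <- cluster_kmeans(X, 2, seed = 1)
  expect_identical(km$unassigned, "r4")
  expect_equal(n_clusters(km), 2L)
})

test_that("k-medoid centers are members minimizing the within-cluster distance sum", {
  mb <- matrix(c(0, 0.1, 10, 10.1), 4, 1, dimnames = list(paste0("r", 1:4), "x"))
  kd <- cluster_kmedoid(mb, 2, seed = 1)
  expect_identical(kd$clusters, list(c("r1", "r2"), c("r3", "r4")))
  med <- attr(kd, "medoids")
  D <- compute_distance(mb, "euclidean")$d
  for (i in seq_along(kd$clusters)) {
    cl <- kd$clusters[[i]]
    expect_true(med[i] %in% cl)
    msum <- sum(D[med[i], cl])
    for (other in cl) expect_lte(msum, sum(D[other, cl]) + 1e-12)
  }
  one <- cluster_kmedoid(mb[1, , drop = FALSE], 1, seed = 1)
  expect_identical(attr(one, "medoids"), "r1")
})

# -- silhouette + select_k ----------------------------------------------------

test_that("silhouette widths follow the closed form", {
  mb <- matrix(c(0, 0.1, 10, 10.1), 4, 1, dimnames = list(paste0("r", 1:4), "x"))
  D <- compute_distance(mb, "euclidean")
  asg <- cluster_assignment(list(c("r1", "r2"), c("r3", "r4")))
  s <- silhouette_widths(asg, D)
  expect_equal(s$widths[["r1"]], (10.05 - 0.1) / 10.05)
  expect_equal(s$mean, mean(c((10.05 - 0.1) / 10.05, (9.95 - 0.1) / 9.95,
                              (9.95 - 0.1) / 9.95, (10.05 - 0.1) / 10.05)))
  expect_gt(s$mean, 0.98)

  # identical points split in two: a = b = 0 handled as 0
  ident <- matrix(0, 4, 1, dimnames = list(paste0("r", 1:4), "x"))
  s0 <- silhouette_widths(cluster_assignment(list(c("r1", "r2"), c("r3", "r4"))),
                          compute_distance(ident, "euclidean"))
  expect_equal(s0$mean, 0)

  # singleton clusters get 0; values bounded in [-1, 1]
  set.seed(8)
  X <- matrix(rnorm(20), 10, 2, dimnames = list(sprintf("r%02d", 1:10), NULL))
  asg3 <- cluster_assignment(list(sprintf("r%02d", 1:5), sprintf("r%02d", 6:9), "r10"))
  sr <- silhouette_widths(asg3, compute_distance(X, "euclidean"))
  expect_equal(sr$widths[["r10"]], 0)
  expect_true(all(sr$widths >= -1 & sr$widths <= 1))

  expect_error(silhouette_widths(cluster_assignment(list(rownames(X))),
                                 compute_distance(X, "euclidean")),
               "single-cluster")
})

test_that("select_k maximizes the mean silhouette over the requested range", {
  # two-blob data: silhouettes computed for both k confirm k = 2
  mb <- matrix(c(0, 0.1, 10, 10.1), 4, 1, dimnames = list(paste0("r", 1:4), "x"))
  # need k_range within [2, rows-1] -> use 5 points
  m5 <- matrix(c(0, 0.1, 0.2, 10, 10.1), 5, 1,
               dimnames = list(paste0("r", 1:5), "x"))
  sk <- select_k(m5, "kmeans", k_range = c(2, 3), seed = 1)
  expect_equal(sk$k, 2L)
  expect_equal(nrow(sk$silhouettes), 2L)

  # three well-separated 1-D blobs
  v <- c(0, 0.1, 0.2, 50, 50.1, 50.2, 100, 100.1, 100.2)
  m9 <- matrix(v, 9, 1, dimnames = list(sprintf("r%d", 1:9), "x"))
  sk3 <- select_k(m9, "kmeans", k_range = c(2, 5), seed = 1)
  expect_equal(sk3$k, 3L)
  expect_equal(sk3$silhouettes$k, 2:5)
  sk3m <- select_k(m9, "kmedoid", k_range = c(2, 5), seed = 1)
  expect_equal(sk3m$k, 3L)

  expect_error(select_k(m5, "kmeans", k_range = c(2, 10)), "k_range")
})

# -- EMAP-style edge-attribute workflow ---------------------------------------

test_that("clustering a symmetric edge-attribute adjacency reproduces the EMAP workflow", {
  truth <- setNames(rep(1:3, each = 4), sprintf("g%02d", 1:12))
  s <- similarity_from_labels(truth, s_in = 5, s_out = 0.5, jitter_sd = 0.3,
                              seed = 12)
  net_edges <- which(upper.tri(s), arr.ind = TRUE)
  net <- weighted_network(edge_df(rownames(s)[net_edges[, 1]],
                                  rownames(s)[net_edges[, 2]],
                                  s[net_edges]))
  A <- adjacency_from_edge_attribute(net)
  d <- compute_distance(A, "uncentered")
  tree <- cluster_hierarchical(d, "average")
  asg <- cut_tree(tree, k = 3)
  expect_equal(ari(asg, truth), 1.0)
})
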