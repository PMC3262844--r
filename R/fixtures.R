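#' Planted-partition (stochastic block model) network generator
#'
#' Benchmark graphs with known community structure: every intra-block node
#' pair receives an edge with probability `p_in`, every inter-block pair
#' with probability `p_out`; edge weights are drawn from the supplied
#' samplers (constant 1 by default).  Node ids are zero-padded
#' (`n01, n02, ...`) so lexicographic and numeric order coincide.  Pure
#' function of its arguments including `seed`.
#'
#' @param block_sizes integer vector of block sizes
#' @param p_in,p_out edge probabilities in \[0, 1\]
#' @param weight_in,weight_out functions `n -> numeric(n)` sampling edge
#'   weights (evaluated inside the seeded RNG scope)
#' @param seed integer seed
#' @return list with `network` (a `weighted_network`) and `labels` (named
#'   integer vector of planted block labels)
#' @export
planted_partition <- function(block_sizes, p_in, p_out,
                              weight_in = function(n) rep(1, n),
                              weight_out = function(n) rep(1, n),
                              seed = 42) {
  if (any(block_sizes < 1)) stop_config("block sizes must be positive")
  if (p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1) {
    stop_config("probabilities must be in [0, 1]")
  }
  n <- sum(block_sizes)
  width <- max(2L, nchar(as.character(n)))
  ids <- sprintf(paste0("n%0", width, "d"), seq_len(n))
  labels <- stats::setNames(rep(seq_along(block_sizes), block_sizes), ids)

  withr::with_seed(seed, {
    pairs_i <- integer(0); pairs_j <- integer(0); intra <- logical(0)
    for (i in seq_len(n - 1L)) {
      j <- (i + 1L):n
      same <- labels[i] == labels[j]
      p <- ifelse(same, p_in, p_out)
      draw <- stats::runif(length(j)) < p
      pairs_i <- c(pairs_i, rep(i, sum(draw)))
      pairs_j <- c(pairs_j, j[draw])
      intra <- c(intra, same[draw])
    }
    w <- numeric(length(pairs_i))
    if (any(intra)) w[intra] <- weight_in(sum(intra))
    if (any(!intra)) w[!intra] <- weight_out(sum(!intra))
    net <- weighted_network(data.frame(source = ids[pairs_i], target = ids[pairs_j],
                                       weight = w, stringsAsFactors = FALSE),
                            nodes = ids)
    list(network = net, labels = labels)
  })
}

#' Block-structured synthetic expression matrix
#'
#' Emulates a normalized multi-condition expression data set with planted
#' co-expression blocks: genes and arrays are partitioned into matching
#' groups; a gene's mean is `+effect_size` on arrays of its own group and
#' `-effect_size` elsewhere, Gaussian noise is added, cells go missing
#' independently with `missing_rate`, and every row is median-centered
#' (log-ratio-like output).  Pure function of its arguments including
#' `seed`.
#'
#' @param n_genes,n_arrays matrix dimensions
#' @param n_blocks number of planted gene/array groups (genes and arrays
#'   are split as evenly as possible)
#' @param effect_size block mean offset (in log2-like units)
#' @param noise_sd Gaussian noise standard deviation
#' @param missing_rate Bernoulli missing probability in \[0, 1\]
#' @param seed integer seed
#' @return list with `matrix` (an `attribute_matrix`), `labels` (gene
#'   blocks) and `array_labels`
#' @export
synthetic_expression <- function(n_genes, n_arrays, n_blocks, effect_size = 2,
                                 noise_sd = 0.5, missing_rate = 0, seed = 42) {
  if (missing_rate < 0 || missing_rate > 1) stop_config("missing_rate must be in [0, 1]")
  if (n_blocks > n_genes || n_blocks > n_arrays) {
    stop_config("n_blocks cannot exceed n_genes or n_arrays")
  }
  gw <- max(2L, nchar(as.character(n_genes)))
  gene_ids <- sprintf(paste0("g%0", gw, "d"), seq_len(n_genes))
  array_ids <- sprintf("array%02d", seq_len(n_arrays))
  gene_block <- stats::setNames(rep(seq_len(n_blocks), length.out = n_genes)[
    order(rep(seq_len(n_blocks), length.out = n_genes))], gene_ids)
  array_block <- stats::setNames(rep(seq_len(n_blocks), length.out = n_arrays)[
    order(rep(seq_len(n_blocks), length.out = n_arrays))], array_ids)

  withr::with_seed(seed, {
    mu <- outer(gene_block, array_block,
                function(g, a) ifelse(g == a, effect_size, -effect_size))
    v <- mu + stats::rnorm(n_genes * n_arrays, sd = noise_sd)
    if (missing_rate > 0) {
      v[stats::runif(length(v)) < missing_rate] <- NA_real_
    }
    dimnames(v) <- list(gene_ids, array_ids)
    med <- apply(v, 1, stats::median, na.rm = TRUE)
    med[!is.finite(med)] <- 0
    v <- sweep(v, 1, med, "-")
    list(matrix = attribute_matrix(v), labels = gene_block,
         array_labels = array_block)
  })
}

#' Block similarity matrix from known labels
#'
#' Toy all-vs-all similarity (BLAST-like) for testing the similarity-matrix
#' algorithms: `s_in` within groups, `s_out` between, symmetric Gaussian
#' jitter, diagonal fixed at `s_in`.  Negative jittered values are clamped
#' to 0 so the result remains a valid non-negative similarity.
#'
#' @param labels named integer vector (node id -> group)
#' @param s_in,s_out within/between similarities (`s_in > s_out`)
#' @param jitter_sd standard deviation of the symmetric jitter
#' @param seed integer seed
#' @return symmetric numeric matrix with node ids as dimnames
#' @export
similarity_from_labels <- function(labels, s_in = 1, s_out = 0, jitter_sd = 0,
                                   seed = 42) {
  if (s_in <= s_out) stop_config("s_in must exceed s_out")
  ids <- names(labels)
  if (is.null(ids)) stop_config("labels must be named by node id")
  n <- length(ids)
  s <- outer(labels, labels, function(a, b) ifelse(a == b, s_in, s_out))
  dimnames(s) <- list(ids, ids)
  if (jitter_sd > 0) {
    withr::with_seed(seed, {
      jit <- matrix(stats::rnorm(n * n, sd = jitter_sd), n, n)
      jit[lower.tri(jit)] <- t(jit)[lower.tri(jit)]
      s <- s + jit
    })
  }
  diag(s) <- s_in
  pmax(s, 0)
}
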