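#' Algorithm registry and default parameters
#'
#' The network algorithms take a `weighted_network`; the similarity-matrix
#' algorithms (`ap`, `transclust`, `scps`) take the symmetric adjacency
#' built from the edge attribute; the attribute algorithms take a matrix.
#' @return named list of defaults for one algorithm, or the registry names
#' @param algorithm algorithm name
#' @export
describe_algorithm <- function(algorithm = NULL) {
  reg <- list(
    mcl = list(inflation = 2, pruning_threshold = 1e-20, max_residual = 1e-6,
               max_iterations = 16, loop_policy = "max_incident"),
    ap = list(preference = "median", damping = 0.9, max_iterations = 1000,
              convergence_window = 50),
    mcode = list(vertex_weight_percentage = 0.2, haircut = TRUE, fluff = FALSE,
                 fluff_density_cutoff = 0.5, k_core = 2, max_depth = 100),
    gn = list(),
    cc = list(),
    transclust = list(threshold = 0.5, exact_limit = 8),
    scps = list(n_clusters = "auto", kmeans_restarts = 10, seed = 42),
    hier = list(metric = "euclidean", linkage = "average"),
    kmeans = list(k = NULL, metric = "euclidean", n_init = 10,
                  max_iterations = 100, seed = 42),
    kmedoid = list(k = NULL, metric = "euclidean", n_init = 10,
                   max_iterations = 100, seed = 42))
  if (is.null(algorithm)) return(names(reg))
  if (!algorithm %in% names(reg)) stop_config("unknown algorithm: ", algorithm)
  reg[[algorithm]]
}

#' Run a full clustering pipeline from a configuration
#'
#' Executes read -> weight conversion -> cutoff -> cluster -> export in one
#' deterministic, scriptable step (the command-line entry point is a thin
#' wrapper around this function).  The effective configuration is echoed to
#' the log for provenance.  Unknown configuration keys are rejected.
#'
#' Config keys: `input` (edge list / SIF / matrix path), `input_type`
#' (`"network"` or `"matrix"`; inferred from the algorithm when missing),
#' `weight_column`, `conversion` (see [convert_weights()]), `cutoff`
#' (numeric or `"heuristic"`), `cutoff_bins`, `algorithm` (see
#' [describe_algorithm()]), `params` (list of algorithm parameters),
#' `metric`, `normalize` (steps for [normalize_matrix()]), `output_prefix`,
#' `seed`.
#'
#' @param config named list (see above)
#' @return invisible list with `assignment`, `files` (paths written) and
#'   the effective `config`
#' @export
run_pipeline <- function(config) {
  known <- c("input", "input_type", "weight_column", "conversion", "cutoff",
             "cutoff_bins", "algorithm", "params", "metric", "normalize",
             "output_prefix", "seed", "linkage", "k", "restore_inter_cluster")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0L) {
    stop_config("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  algorithm <- config$algorithm %||% stop_config("config needs an 'algorithm'")
  if (!algorithm %in% describe_algorithm()) stop_config("unknown algorithm: ", algorithm)
  input <- config$input %||% stop_config("config needs an 'input' path")
  if (!file.exists(input)) stop_data("input file not found: ", input)
  seed <- config$seed %||% 42
  params <- utils::modifyList(describe_algorithm(algorithm), config$params %||% list())
  matrix_algos <- c("hier", "kmeans", "kmedoid")
  input_type <- config$input_type %||%
    if (algorithm %in% matrix_algos) "matrix" else "network"
  ck_message("config: algorithm=", algorithm, " input=", input,
             " conversion=", config$conversion %||% "none",
             " cutoff=", config$cutoff %||% "none", " seed=", seed)

  files <- character(0)
  prefix <- config$output_prefix %||% "clustkit_out"
  t0 <- Sys.time()

  if (input_type == "network") {
    net <- read_edge_list(input, weight_column = config$weight_column)
    net <- convert_weights(net, config$conversion %||% "none")
    if (!is.null(config$cutoff)) {
      cutoff <- if (identical(config$cutoff, "heuristic")) {
        h <- edge_weight_histogram(net, n_bins = config$cutoff_bins %||% 100,
                                   conversion = config$conversion %||% "none")
        heuristic_cutoff(h)
      } else {
        as.numeric(config$cutoff)
      }
      ck_message("applying edge-weight cutoff ", format(cutoff))
      net <- apply_cutoff(net, cutoff)
    }
    assignment <- switch(algorithm,
      mcl = cluster_mcl(net, inflation = params$inflation,
                        pruning_threshold = params$pruning_threshold,
                        max_residual = params$max_residual,
                        max_iterations = params$max_iterations,
                        loop_policy = params$loop_policy),
      cc = cluster_connected_components(net),
      gn = cluster_girvan_newman(net),
      mcode = cluster_mcode(net,
                            vertex_weight_percentage = params$vertex_weight_percentage,
                            haircut = params$haircut, fluff = params$fluff,
                            fluff_density_cutoff = params$fluff_density_cutoff,
                            k_core = params$k_core, max_depth = params$max_depth),
      ap = cluster_ap(adjacency_from_edge_attribute(net),
                      preference = params$preference, damping = params$damping,
                      max_iterations = params$max_iterations,
                      convergence_window = params$convergence_window),
      transclust = cluster_transclust(adjacency_from_edge_attribute(net),
                                      threshold = params$threshold,
                                      exact_limit = params$exact_limit),
      scps = cluster_scps(adjacency_from_edge_attribute(net),
                          n_clusters = params$n_clusters,
                          kmeans_restarts = params$kmeans_restarts, seed = seed))
    out_net <- build_cluster_network(net, assignment,
                                     restore_inter_cluster =
                                       isTRUE(config$restore_inter_cluster))
    f <- paste0(prefix, ".cluster_network.tsv")
    write_edge_list(out_net, f)
    files <- c(files, f)
  } else {
    mat <- read_matrix(input)
    if (!is.null(config$normalize)) mat <- normalize_matrix(mat, config$normalize)
    metric <- config$metric %||% params$metric %||% "euclidean"
    if (algorithm == "hier") {
      keep <- setdiff(rownames(mat$values), rows_all_missing(mat))
      sub <- attribute_matrix(mat$values[keep, , drop = FALSE])
      d <- compute_distance(sub, metric)
      tree <- cluster_hierarchical(d, linkage = config$linkage %||% params$linkage,
                                   matrix = sub)
      f <- write_treeview(sub, row_dendrogram = tree, path_prefix = prefix)
      files <- c(files, f)
      assignment <- if (!is.null(config$k)) cut_tree(tree, k = config$k)
                    else cluster_assignment(list(keep))
    } else {
      fn <- if (algorithm == "kmeans") cluster_kmeans else cluster_kmedoid
      k <- config$k %||% params$k %||% stop_config("k-partition algorithms need 'k'")
      assignment <- fn(mat, k = k, metric = metric, n_init = params$n_init,
                       max_iterations = params$max_iterations, seed = seed)
    }
  }

  f <- paste0(prefix, ".assignment.tsv")
  write_assignment(assignment, f)
  files <- c(files, f)
  sizes <- cluster_sizes(assignment)
  ck_message("clusters: ", length(sizes), "; top sizes: ",
             paste(utils::head(sizes, 5), collapse = " "),
             "; wall time ", format(round(as.numeric(difftime(Sys.time(), t0,
                                                              units = "secs")), 2)), "s")
  invisible(list(assignment = assignment, files = files,
                 config = utils::modifyList(config, list(params = params))))
}
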