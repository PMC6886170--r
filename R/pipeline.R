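#' Run the clustering, response-time and scheduling stages
#'
#' The post-consensus half of the pipeline: build concatenated profiles for
#' the given genes, cluster them with [spherical_kmeans()], drop clusters
#' with fewer than `min_cluster_size` members, locate each cluster's
#' response-time vector ([init_rt()] then [hill_climb_rt()]), and assemble
#' the response schedule ([build_schedule()]).
#'
#' @param dataset Normalized [expression_dataset()].
#' @param genes Genes to cluster (typically the consensus DEGs).
#' @param k Number of clusters.
#' @param seed Integer seed (clustering restarts are derived from it).
#' @param n_restarts,max_iter Spherical k-means controls.
#' @param min_cluster_size Minimum cluster membership kept.
#' @param move_radius,per_sample_tstat,variance_floor Response-time search
#'   controls (see [hill_climb_rt()]).
#' @param exact_schedule Use the exact longest-chain schedule instead of
#'   the greedy scan.
#' @return List with `result` (a [result_table()]), `clusters` (with `rt`
#'   and `quality` filled) and `schedule`.
#' @export
cluster_and_schedule <- function(dataset, genes, k, seed, n_restarts = 10,
                                 max_iter = 100, min_cluster_size = 3,
                                 move_radius = 1, per_sample_tstat = FALSE,
                                 variance_floor = 1e-8,
                                 exact_schedule = FALSE) {
  profiles <- build_profiles(dataset, genes)
  clusters <- spherical_kmeans(profiles, k, seed = seed + 100000L,
                               n_restarts = n_restarts, max_iter = max_iter)
  clusters <- filter_small_clusters(clusters, min_cluster_size)
  for (i in seq_along(clusters)) {
    init <- init_rt(dataset, clusters[[i]]$members)
    hc <- hill_climb_rt(dataset, clusters[[i]]$members, init,
                        move_radius = move_radius,
                        variance_floor = variance_floor,
                        per_sample = per_sample_tstat)
    clusters[[i]]$rt <- hc$rt
    clusters[[i]]$quality <- hc$score
  }
  schedule <- build_schedule(clusters, exact = exact_schedule)
  result <- collect_result(schedule, clusters, sample_ids(dataset))
  list(result = result, clusters = clusters, schedule = schedule)
}

#' Run the full integration pipeline
#'
#' Executes the four stages on a multi-sample time-series dataset:
#' normalization, consensus DEG detection (per-sample tests plus the
#' permutation test on the gene-by-sample DEG matrix), co-expression
#' clustering with cluster-count selection, response-time detection and
#' response scheduling.  Outputs (`genes.tsv`, `clusters.tsv`,
#' `run_manifest.txt`) are written when `out_dir` is given; runs with
#' identical inputs, parameters and seed produce identical files.
#'
#' @param dataset An [expression_dataset()] of raw or pre-normalized values.
#' @param scale_method,base_method,log_base,per_sample_scale Normalization
#'   (see [normalize_dataset()]).  Synthetic data from [simulate_dataset()]
#'   is already on an additive baseline-zero scale: use defaults.
#' @param alpha Significance level for both the per-sample DEG tests and
#'   the consensus permutation test.
#' @param n_permutations Permutations for [consensus_test()].
#' @param k Fixed number of clusters; when `NULL`, selected by [select_k()]
#'   over `k_grid`.
#' @param k_grid Candidate cluster counts for selection.  Default: 50 to
#'   half the number of consensus DEGs in steps of 50 when there are at
#'   least 100 consensus DEGs, otherwise 2 to `min(20, n/2)`.
#' @param moderate_var Variance moderation in the per-sample tests (see
#'   [detect_sample_degs()]).
#' @param seed Integer seed (mandatory); all stochastic stages derive their
#'   seeds from it.
#' @param out_dir Optional output directory.
#' @param verbose Emit per-stage progress messages.
#' @inheritParams cluster_and_schedule
#' @return A `pipeline_run`: list with `result`, `consensus`, `clusters`,
#'   `schedule`, `k` and `manifest`.
#' @export
run_pipeline <- function(dataset,
                         scale_method = c("none", "quantile"),
                         base_method = c("linear", "logfold"),
                         log_base = 2, per_sample_scale = FALSE,
                         alpha = 0.05, n_permutations = 1000,
                         k = NULL, k_grid = NULL,
                         n_restarts = 10, max_iter = 100,
                         min_cluster_size = 3, move_radius = 1,
                         per_sample_tstat = FALSE, moderate_var = FALSE,
                         exact_schedule = FALSE, variance_floor = 1e-8,
                         seed, out_dir = NULL, verbose = TRUE) {
  if (missing(seed)) stop("`seed` is mandatory")
  scale_method <- match.arg(scale_method)
  base_method <- match.arg(base_method)
  say <- function(...) if (verbose) message(sprintf(...))

  norm <- normalize_dataset(dataset, scale_method, base_method, log_base,
                            per_sample_scale)

  deg_sets <- list()
  for (s in sample_ids(norm)) {
    deg_sets[[s]] <- tryCatch(
      detect_sample_degs(norm, s, alpha = alpha,
                         variance_floor = variance_floor,
                         moderate_var = moderate_var),
      untestable_sample = function(e) {
        warning(conditionMessage(e), call. = FALSE)
        NULL
      })
  }
  deg_sets <- Filter(Negate(is.null), deg_sets)
  if (length(deg_sets) == 0L)
    stop("consensus stage failed: no testable samples")
  deg_matrix <- build_deg_matrix(deg_sets, norm$genes)
  consensus <- consensus_test(deg_matrix, n_permutations = n_permutations,
                              seed = seed, alpha = alpha)
  say("consensus: %d DEGs across %d testable samples",
      length(consensus$consensus_genes), ncol(deg_matrix))

  manifest <- list(
    scale_method = scale_method, base_method = base_method,
    log_base = log_base, per_sample_scale = per_sample_scale,
    alpha = alpha, n_permutations = n_permutations,
    n_restarts = n_restarts, max_iter = max_iter,
    min_cluster_size = min_cluster_size, move_radius = move_radius,
    per_sample_tstat = per_sample_tstat, moderate_var = moderate_var,
    exact_schedule = exact_schedule, variance_floor = variance_floor,
    seed = seed, n_genes = length(dataset$genes),
    n_samples = length(dataset$design),
    n_consensus_degs = length(consensus$consensus_genes))

  finish <- function(result, clusters, schedule, k_used) {
    manifest$k <- if (is.null(k_used)) NA else k_used
    manifest$n_scheduled_clusters <- nrow(schedule$entries)
    manifest$n_response_order_degs <- nrow(result)
    manifest$n_phases <- if (nrow(schedule$entries))
      max(schedule$entries$phase) else 0L
    if (!is.null(out_dir)) {
      write_results(result, out_dir)
      write_manifest(manifest, file.path(out_dir, "run_manifest.txt"))
    }
    structure(list(result = result, consensus = consensus,
                   clusters = clusters, schedule = schedule,
                   k = manifest$k, manifest = manifest),
              class = "pipeline_run")
  }

  if (length(consensus$consensus_genes) == 0L) {
    warning("no consensus DEGs at alpha = ", alpha, "; returning empty result")
    schedule <- build_schedule(list())
    return(finish(collect_result(schedule, list(), sample_ids(norm)),
                  list(), schedule, NULL))
  }

  if (is.null(k)) {
    n <- length(consensus$consensus_genes)
    if (is.null(k_grid)) {
      k_grid <- if (n >= 100) seq(50L, max(50L, n %/% 2L), by = 50L)
                else seq(2L, max(2L, min(20L, n %/% 2L)))
    }
    k <- select_k(norm, consensus, k_grid, seed = seed,
                  n_restarts = n_restarts, max_iter = max_iter,
                  min_cluster_size = min_cluster_size,
                  move_radius = move_radius,
                  per_sample_tstat = per_sample_tstat,
                  variance_floor = variance_floor,
                  exact_schedule = exact_schedule)
    say("selected k = %d from grid of %d candidates", k, length(k_grid))
  }

  stage2 <- cluster_and_schedule(
    norm, consensus$consensus_genes, k = k, seed = seed,
    n_restarts = n_restarts, max_iter = max_iter,
    min_cluster_size = min_cluster_size, move_radius = move_radius,
    per_sample_tstat = per_sample_tstat, variance_floor = variance_floor,
    exact_schedule = exact_schedule)
  say("clustering: %d cluster(s) of >= %d genes", length(stage2$clusters),
      min_cluster_size)
  say("schedule: %d cluster(s) in %d phase(s); %d response-order genes",
      nrow(stage2$schedule$entries),
      if (nrow(stage2$schedule$entries)) max(stage2$schedule$entries$phase)
      else 0L,
      nrow(stage2$result))
  finish(stage2$result, stage2$clusters, stage2$schedule, as.integer(k))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf(
    "<pipeline_run> %d consensus DEGs -> %d cluster(s) -> %d scheduled in %d phase(s) -> %d genes\n",
    length(x$consensus$consensus_genes), length(x$clusters),
    nrow(x$schedule$entries), x$manifest$n_phases, nrow(x$result)))
  invisible(x)
}
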