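#' Configuration for the synthetic multi-sample time-series generator
#'
#' Describes a planted response-order structure: `n_phases` successive
#' response phases, each with `genes_per_phase` responsive genes whose
#' expression is 0 before a per-phase, per-sample change index and shifts
#' to `+-effect_size` (sign fixed per gene) from that index onward, plus
#' `n_null_genes` genes flat at 0.  Sample heterogeneity is emulated by
#' different grid lengths and by per-sample delay offsets that shift all
#' change points of a sample by the same amount — response order across
#' phases is preserved in every sample, which is the structural premise of
#' the method.
#'
#' Change indices are `c[p, i] = p + 1 + delay[i]`, so phase `p` responds at
#' index `p + 1` in an undelayed sample; delays default to
#' `min(i - 1, l_i - n_phases - 1)` and every index stays in `[2, l_i]`.
#'
#' @param n_samples Number of time-series samples `m`.
#' @param n_timepoints Integer vector of grid lengths `l_i` (recycled to
#'   `n_samples`).
#' @param n_phases Number of planted response phases `P`.
#' @param genes_per_phase Responsive genes per phase.
#' @param n_null_genes Unresponsive genes.
#' @param effect_size Magnitude of the post-response shift (expression
#'   units, default 5).
#' @param noise_sd Replicate noise standard deviation (same units).
#' @param n_replicates Replicates per time point (scalar or per sample).
#' @param sample_delays Non-negative per-sample shift of all change
#'   indices; `NULL` for the default above.
#' @param shape `"step"` (sustained shift, the canonical model) or
#'   `"sigmoid"` (smooth ramp, for robustness checks).
#' @param noise `"gaussian"` or `"t3"` (scaled Student t, 3 df —
#'   heavy-tailed robustness option).
#' @param seed Integer seed (mandatory).
#' @return A `simulation_config`.
#' @export
simulation_config <- function(n_samples = 4, n_timepoints = c(6, 7, 8, 10),
                              n_phases = 5, genes_per_phase = 10,
                              n_null_genes = 200, effect_size = 5,
                              noise_sd = 0, n_replicates = 3,
                              sample_delays = NULL,
                              shape = c("step", "sigmoid"),
                              noise = c("gaussian", "t3"), seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  shape <- match.arg(shape); noise <- match.arg(noise)
  m <- as.integer(n_samples)
  l <- rep_len(as.integer(n_timepoints), m)
  P <- as.integer(n_phases)
  if (P < 1L) stop("`n_phases` must be >= 1")
  if (genes_per_phase < 0 || n_null_genes < 0) stop("negative gene counts")
  if (genes_per_phase * P + n_null_genes == 0L) stop("empty gene set")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (any(l < P + 1L))
    stop("every sample needs at least n_phases + 1 time points")
  if (is.null(sample_delays))
    sample_delays <- pmin(seq_len(m) - 1L, l - P - 1L)
  sample_delays <- as.integer(rep_len(sample_delays, m))
  if (any(sample_delays < 0)) stop("`sample_delays` must be >= 0")
  change <- outer(seq_len(P) + 1L, sample_delays, `+`)  # P x m
  if (any(change > matrix(l, P, m, byrow = TRUE)))
    stop("change indices exceed a sample's grid; reduce `sample_delays`")
  structure(list(n_samples = m, n_timepoints = l, n_phases = P,
                 genes_per_phase = as.integer(genes_per_phase),
                 n_null_genes = as.integer(n_null_genes),
                 effect_size = effect_size, noise_sd = noise_sd,
                 n_replicates = rep_len(as.integer(n_replicates), m),
                 sample_delays = sample_delays, change_index = change,
                 shape = shape, noise = noise, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a heterogeneous multi-sample time-series dataset
#'
#' Generates the dataset described by a [simulation_config()] together with
#' its ground truth.  Values are already on an additive, baseline-zero
#' scale, so the natural normalization downstream is `scale_method =
#' "none"`, `base_method = "linear"`.  Deterministic given the config seed.
#'
#' @param config A [simulation_config()].
#' @return List with `dataset` (an [expression_dataset()]) and `truth`
#'   (a `ground_truth`: `gene_phase` — named phase index, `NA` for null
#'   genes —, `change_index`, `signs`, `responsive_genes`, `config`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  P <- config$n_phases; m <- config$n_samples
  resp <- if (config$genes_per_phase > 0)
    paste0("g_p", rep(seq_len(P), each = config$genes_per_phase), "_",
           rep(seq_len(config$genes_per_phase), P))
  else character()
  nulls <- if (config$n_null_genes > 0)
    paste0("null_", seq_len(config$n_null_genes)) else character()
  genes <- c(resp, nulls)
  phase <- c(rep(seq_len(P), each = config$genes_per_phase),
             rep(NA_integer_, config$n_null_genes))
  names(phase) <- genes
  # Signs alternate within each phase: every phase plants a balanced pair of
  # induced and repressed subgroups, each large enough to survive the
  # minimum-cluster-size filter (co-expression clustering separates the two
  # signs, since opposite steps are antipodal in cosine similarity).
  signs <- stats::setNames(rep_len(c(1, -1), length(resp)), resp)

  grids <- lapply(seq_len(m), function(i) {
    l <- config$n_timepoints[i]
    c(0, 2^(seq_len(l - 1L) - 1L) / 2)    # 0, 0.5, 1, 2, 4, ... hours
  })
  design <- lapply(seq_len(m), function(i)
    sample_design(sprintf("s%d", i), grids[[i]], config$n_replicates[i]))
  names(design) <- vapply(design, `[[`, character(1), "sample_id")

  values <- list()
  for (i in seq_len(m)) {
    l <- config$n_timepoints[i]; nr <- config$n_replicates[i]
    mu <- matrix(0, length(genes), l)
    for (g in seq_along(resp)) {
      cp <- config$change_index[phase[[resp[g]]], i]
      mu[g, ] <- switch(config$shape,
        step = signs[g] * config$effect_size * (seq_len(l) >= cp),
        sigmoid = signs[g] * config$effect_size *
          stats::plogis(3 * (seq_len(l) - cp + 0.5)))
    }
    arr <- array(NA_real_, dim = c(length(genes), l, nr))
    for (k in seq_len(nr)) {
      eps <- switch(config$noise,
        gaussian = stats::rnorm(length(genes) * l, sd = config$noise_sd),
        t3 = config$noise_sd * stats::rt(length(genes) * l, df = 3))
      arr[, , k] <- mu + matrix(eps, length(genes), l)
    }
    values[[names(design)[i]]] <- arr
  }
  dataset <- expression_dataset(genes, design, values)
  truth <- structure(list(gene_phase = phase,
                          change_index = config$change_index,
                          signs = signs, responsive_genes = resp,
                          config = config),
                     class = "ground_truth")
  list(dataset = dataset, truth = truth)
}

#' Score a result against the planted ground truth
#'
#' @param result A [result_table()] from the pipeline.
#' @param truth A `ground_truth` from [simulate_dataset()].
#' @return List with `precision`, `recall`, `f1` (0 when nothing is
#'   recovered), `kendall_tau` (tau-b between recovered and planted phase
#'   indices over the shared genes; 1 when both are constant, `NA` when
#'   fewer than 2 genes are shared) and `phase_count_error`.
#' @export
truth_metrics <- function(result, truth) {
  found <- unique(result$gene_id)
  planted <- truth$responsive_genes
  tp <- length(intersect(found, planted))
  precision <- if (length(found)) tp / length(found) else 0
  recall <- if (length(planted)) tp / length(planted) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  inter <- intersect(found, planted)
  tau <- NA_real_
  if (length(inter) >= 2L) {
    rec <- result$phase[match(inter, result$gene_id)]
    pla <- truth$gene_phase[inter]
    if (stats::var(rec) == 0 && stats::var(pla) == 0) tau <- 1
    else tau <- suppressWarnings(stats::cor(rec, pla, method = "kendall"))
  }
  n_phases_found <- if (nrow(result)) length(unique(result$phase)) else 0L
  list(precision = precision, recall = recall, f1 = f1, kendall_tau = tau,
       phase_count_error = abs(n_phases_found - truth$config$n_phases))
}
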