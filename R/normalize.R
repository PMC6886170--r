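#' Quantile normalization across replicate arrays
#'
#' Makes the value distribution identical across all replicate arrays (one
#' array = one sample/time/replicate column over genes) by mapping each
#' column's ranks onto the mean of the sorted columns.  Ties within a
#' column receive the average of the target values over the tied ranks.
#'
#' @param dataset An [expression_dataset()].
#' @param per_sample Normalize within each time-series sample's own columns
#'   instead of jointly across all samples (default joint).
#' @return The dataset with normalized values.
#' @export
quantile_normalize <- function(dataset, per_sample = FALSE) {
  if (length(dataset$genes) == 1L) {
    warning("quantile normalization skipped: only one gene (ranks trivial)")
    return(dataset)
  }
  cols <- list()  # each a numeric vector over genes
  idx <- list()   # (sample, j, k) locator per column
  for (s in sample_ids(dataset)) {
    d <- dataset$design[[s]]
    for (j in seq_along(d$time_points)) {
      for (k in seq_len(d$n_replicates[j])) {
        cols[[length(cols) + 1L]] <- dataset$values[[s]][, j, k]
        idx[[length(idx) + 1L]] <- list(s = s, j = j, k = k)
      }
    }
  }
  groups <- if (per_sample)
    split(seq_along(cols), vapply(idx, `[[`, character(1), "s"))
  else
    list(seq_along(cols))
  for (grp in groups) {
    mat <- do.call(cbind, cols[grp])
    norm <- .quantile_normalize_matrix(mat)
    for (i in seq_along(grp)) cols[[grp[i]]] <- norm[, i]
  }
  for (i in seq_along(cols)) {
    loc <- idx[[i]]
    dataset$values[[loc$s]][, loc$j, loc$k] <- cols[[i]]
  }
  dataset
}

# Column-wise quantile normalization with average-tie handling.
.quantile_normalize_matrix <- function(mat) {
  target <- rowMeans(apply(mat, 2, sort))
  out <- mat
  for (i in seq_len(ncol(mat))) {
    r <- rank(mat[, i], ties.method = "average")
    out[, i] <- (target[floor(r)] + target[ceiling(r)]) / 2
  }
  out
}

#' Base normalization: subtract the baseline mean
#'
#' Zeroes the pre-treatment level: every value `e[g,i,j,k]` is replaced by
#' `e[g,i,j,k] - mean_k(e[g,i,1,k])`, so the replicate mean at the first
#' time point becomes exactly 0 for every gene and sample.  Appropriate for
#' data on an additive (e.g. log microarray intensity) scale.
#'
#' @param dataset An [expression_dataset()].
#' @return The base-normalized dataset.
#' @export
base_normalize_linear <- function(dataset) {
  transform_values(dataset, function(v, d) {
    base <- rowMeans(v[, 1, seq_len(d$n_replicates[1]), drop = FALSE])
    sweep(v, 1, base)
  })
}

#' Base normalization: log fold change against baseline
#'
#' For non-negative count-like data: every value is replaced by
#' `log(e+1) - mean_k(log(e[g,i,1,k]+1))` in base `log_base`.
#'
#' @param dataset An [expression_dataset()] with non-negative raw values.
#' @param log_base Logarithm base (> 1); default 2, the fold-change
#'   convention.
#' @return The base-normalized dataset.
#' @export
base_normalize_logfold <- function(dataset, log_base = 2) {
  if (!is.numeric(log_base) || log_base <= 1)
    stop("`log_base` must be > 1")
  for (s in sample_ids(dataset)) {
    v <- dataset$values[[s]]
    if (any(v < 0, na.rm = TRUE)) {
      bad <- which(v < 0, arr.ind = TRUE)[1, ]
      stop(sprintf(
        "negative value for gene '%s', sample '%s', time index %d, replicate %d: log fold change needs non-negative input",
        dataset$genes[bad[1]], s, bad[2], bad[3]))
    }
  }
  dataset <- transform_values(dataset, function(v, d) log(v + 1) / log(log_base))
  base_normalize_linear(dataset)
}

#' Apply the configured normalization pipeline
#'
#' Scale normalization (quantile or none) followed by base normalization
#' (linear subtraction or log fold change) against the first time point.
#'
#' @param dataset An [expression_dataset()].
#' @param scale_method `"quantile"` or `"none"`.
#' @param base_method `"linear"` (additive-scale data) or `"logfold"`
#'   (non-negative count-like data).
#' @param log_base Base for `base_method = "logfold"`.
#' @param per_sample_scale Restrict quantile normalization within each
#'   sample's own columns.
#' @return The normalized dataset.
#' @export
normalize_dataset <- function(dataset,
                              scale_method = c("quantile", "none"),
                              base_method = c("linear", "logfold"),
                              log_base = 2, per_sample_scale = FALSE) {
  scale_method <- match.arg(scale_method)
  base_method <- match.arg(base_method)
  if (scale_method == "quantile")
    dataset <- quantile_normalize(dataset, per_sample = per_sample_scale)
  switch(base_method,
         linear = base_normalize_linear(dataset),
         logfold = base_normalize_logfold(dataset, log_base))
}
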