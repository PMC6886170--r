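#' Describe one time-series sample
#'
#' A sample design records the measurement grid of a single time-series
#' sample: its ordered time points (in hours, the first being the
#' pre-treatment baseline) and the number of replicates available at each
#' time point.  Downstream computations use only 1-based time-point
#' *indices*; the absolute times are carried for reporting.
#'
#' @param sample_id Character scalar identifying the sample.
#' @param time_points Strictly increasing vector of non-negative times
#'   (hours); the first element is the baseline (time 0 semantics).
#' @param n_replicates Positive integer count of replicates per time point;
#'   a scalar is recycled across all time points.
#' @return An object of class `sample_design`.
#' @export
#' @examples
#' sample_design("s1", c(0, 1, 3, 6), 2)
sample_design <- function(sample_id, time_points, n_replicates) {
  if (!is.character(sample_id) || length(sample_id) != 1L || is.na(sample_id))
    stop("`sample_id` must be a single character string")
  time_points <- as.numeric(time_points)
  if (length(time_points) < 2L)
    stop("a sample needs at least 2 time points (baseline plus one)")
  if (anyNA(time_points) || any(time_points < 0))
    stop("`time_points` must be non-negative and non-missing")
  if (any(diff(time_points) <= 0))
    stop("`time_points` must be strictly increasing")
  n_replicates <- as.integer(n_replicates)
  if (length(n_replicates) == 1L)
    n_replicates <- rep(n_replicates, length(time_points))
  if (length(n_replicates) != length(time_points))
    stop("`n_replicates` must have length 1 or length(time_points)")
  if (anyNA(n_replicates) || any(n_replicates < 1L))
    stop("`n_replicates` must be positive integers")
  structure(
    list(sample_id = sample_id, time_points = time_points,
         n_replicates = n_replicates),
    class = "sample_design"
  )
}

#' @export
print.sample_design <- function(x, ...) {
  cat(sprintf("<sample_design> %s: %d time points (%s h), replicates %s\n",
              x$sample_id, length(x$time_points),
              paste(x$time_points, collapse = ", "),
              paste(x$n_replicates, collapse = "/")))
  invisible(x)
}

#' Multi-sample time-series expression dataset
#'
#' Container for replicated expression values `e[g, i, j, k]` of gene `g`
#' in sample `i` at time-point index `j`, replicate `k`.  Every sample has
#' its own time grid and replicate counts, but all samples share one gene
#' universe.  Values are stored per sample as a `gene x time x replicate`
#' array, padded with `NA` where a time point has fewer replicates than the
#' sample maximum.
#'
#' @param genes Character vector of gene identifiers (no duplicates).
#' @param design List of [sample_design()] objects, one per sample.
#' @param values Named list (one element per sample, names = sample ids) of
#'   3-d numeric arrays `length(genes) x l_i x max(n_replicates)`.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(genes, design, values) {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("empty gene set")
  if (anyDuplicated(genes)) stop("duplicate gene ids")
  if (!is.list(design) || length(design) == 0L)
    stop("`design` must be a non-empty list of sample_design objects")
  ok <- vapply(design, inherits, logical(1), what = "sample_design")
  if (!all(ok)) stop("`design` must contain sample_design objects")
  ids <- vapply(design, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  names(design) <- ids
  if (!setequal(names(values), ids))
    stop("`values` names must match the sample ids in `design`")
  values <- values[ids]
  for (s in ids) {
    d <- design[[s]]
    v <- values[[s]]
    if (!is.array(v) || length(dim(v)) != 3L)
      stop(sprintf("values for sample '%s' must be a 3-d array", s))
    if (dim(v)[1] != length(genes) || dim(v)[2] != length(d$time_points) ||
        dim(v)[3] < max(d$n_replicates))
      stop(sprintf("values for sample '%s' have wrong dimensions", s))
    for (j in seq_along(d$time_points)) {
      nr <- d$n_replicates[j]
      block <- v[, j, seq_len(nr), drop = FALSE]
      if (anyNA(block)) {
        bad <- which(is.na(block), arr.ind = TRUE)[1, ]
        stop(sprintf(
          "incomplete design: missing value for gene '%s', sample '%s', time index %d",
          genes[bad[1]], s, j))
      }
      if (dim(v)[3] > nr && !all(is.na(v[, j, (nr + 1L):dim(v)[3]])))
        stop(sprintf(
          "sample '%s' time index %d has more replicates than its design declares",
          s, j))
    }
    rownames(values[[s]]) <- genes
  }
  structure(list(genes = genes, design = design, values = values),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  l <- vapply(x$design, function(d) length(d$time_points), integer(1))
  cat(sprintf("<expression_dataset> %d genes, %d samples (time points: %s)\n",
              length(x$genes), length(x$design),
              paste(l, collapse = ", ")))
  invisible(x)
}

#' @export
#' @rdname expression_dataset
#' @param x An `expression_dataset`.
sample_ids <- function(x) {
  stopifnot(inherits(x, "expression_dataset"))
  names(x$design)
}

# Replicate-averaged gene x time matrix for one sample.
replicate_mean_matrix <- function(dataset, sample_id) {
  v <- dataset$values[[sample_id]]
  out <- apply(v, c(1, 2), mean, na.rm = TRUE)
  dimnames(out) <- list(dataset$genes, NULL)
  out
}

# All replicate values of one gene in one sample at the given time indices,
# as a plain numeric vector (NA padding dropped).
gene_values <- function(dataset, gene, sample_id, time_idx) {
  v <- dataset$values[[sample_id]][gene, time_idx, , drop = FALSE]
  as.numeric(v[!is.na(v)])
}

# Map over samples applying f(array, design) and rebuild the dataset.
transform_values <- function(dataset, f) {
  vals <- dataset$values
  for (s in names(vals)) vals[[s]] <- f(vals[[s]], dataset$design[[s]])
  dataset$values <- vals
  dataset
}

#' Subset a dataset to a gene set
#'
#' @param dataset An [expression_dataset()].
#' @param genes Character vector of gene ids to keep (order respected).
#' @return An `expression_dataset` restricted to `genes`.
#' @export
subset_genes <- function(dataset, genes) {
  genes <- as.character(genes)
  if (!all(genes %in% dataset$genes))
    stop("unknown gene id: ", setdiff(genes, dataset$genes)[1])
  vals <- lapply(dataset$values, function(v) v[genes, , , drop = FALSE])
  expression_dataset(genes, dataset$design, vals)
}
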