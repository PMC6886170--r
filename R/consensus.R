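#' Pooled-variance two-sample t statistic with a variance floor
#'
#' The equal-variance t statistic `(mean(a) - mean(b)) / sqrt(s2 * (1/nA +
#' 1/nB))` where the pooled variance `s2` is bounded below by
#' `variance_floor` so that zero-variance splits (common after noise-free
#' simulation or hard thresholding) yield a large finite statistic instead
#' of `Inf`/`NaN`.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param variance_floor Lower bound on the pooled variance.
#' @return Signed t statistic (`a` minus `b`).
#' @export
#' @examples
#' two_sample_tstat(c(2, 3), c(0, 1))  # 2.828
two_sample_tstat <- function(a, b, variance_floor = 1e-8) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    stop("insufficient replication: both groups need >= 2 values")
  s2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  s2 <- max(s2, variance_floor)
  (mean(a) - mean(b)) / sqrt(s2 * (1 / na + 1 / nb))
}

# Vectorized pooled t over matrix rows (genes).  A, B: genes x replicates.
# Returns list(t, df).  Optional moderation shrinks each gene's pooled
# variance halfway toward the mean pooled variance across genes; equal
# weighting corresponds to an empirical-Bayes posterior whose prior degrees
# of freedom equal the residual degrees of freedom, so the moderated
# statistic is referred to a t distribution with twice the residual df.
row_tstat <- function(A, B, variance_floor = 1e-8, moderate_var = FALSE) {
  na <- ncol(A); nb <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (na - 1)
  vB <- rowSums((B - mB)^2) / (nb - 1)
  s2 <- ((na - 1) * vA + (nb - 1) * vB) / (na + nb - 2)
  df <- na + nb - 2
  if (moderate_var) {
    s2 <- 0.5 * s2 + 0.5 * mean(s2)
    df <- 2 * df
  }
  s2 <- pmax(s2, variance_floor)
  list(t = (mA - mB) / sqrt(s2 * (1 / na + 1 / nb)), df = df)
}

#' Detect single-sample DEGs against the baseline time point
#'
#' For every time index `j >= 2` with at least 2 replicates on both sides,
#' a two-sided equal-variance t test of time `j` versus the baseline (index
#' 1) is computed per gene, with Benjamini-Hochberg correction across genes
#' within each comparison.  A gene is a DEG in the sample if it is
#' significant in at least one comparison.
#'
#' @param dataset A base-normalized (or raw; the test is shift-invariant)
#'   [expression_dataset()].
#' @param sample_id Sample to test.
#' @param alpha Per-comparison BH-adjusted significance level.
#' @param variance_floor Pooled-variance floor shared with
#'   [two_sample_tstat()].
#' @param moderate_var Shrink per-gene variances 50% toward the across-gene
#'   mean variance within each comparison (a light-weight stand-in for
#'   empirical-Bayes moderation).
#' @return Character vector of DEG gene ids.  Errors with condition class
#'   `untestable_sample` when no time point has sufficient replication.
#' @export
detect_sample_degs <- function(dataset, sample_id, alpha = 0.05,
                               variance_floor = 1e-8, moderate_var = FALSE) {
  d <- dataset$design[[sample_id]]
  if (is.null(d)) stop("unknown sample id: ", sample_id)
  v <- dataset$values[[sample_id]]
  testable <- which(seq_along(d$time_points) >= 2L & d$n_replicates >= 2L)
  if (d$n_replicates[1] < 2L || length(testable) == 0L)
    stop(structure(class = c("untestable_sample", "error", "condition"),
                   list(message = sprintf(
                     "sample untestable: '%s' has no time point with >= 2 replicates on both sides of the baseline",
                     sample_id), call = sys.call())))
  B <- v[, 1, seq_len(d$n_replicates[1]), drop = TRUE]
  if (is.null(dim(B))) B <- matrix(B, ncol = d$n_replicates[1])
  hit <- rep(FALSE, length(dataset$genes))
  for (j in testable) {
    A <- v[, j, seq_len(d$n_replicates[j]), drop = TRUE]
    if (is.null(dim(A))) A <- matrix(A, ncol = d$n_replicates[j])
    ts <- row_tstat(A, B, variance_floor, moderate_var)
    p <- 2 * stats::pt(-abs(ts$t), df = ts$df)
    hit <- hit | (stats::p.adjust(p, method = "BH") < alpha)
  }
  dataset$genes[hit]
}

#' Assemble the gene x sample DEG matrix
#'
#' @param per_sample_degs Named list (sample id -> character vector of DEG
#'   gene ids).
#' @param genes Gene universe (row order of the matrix).
#' @return Binary integer matrix, genes x samples.
#' @export
build_deg_matrix <- function(per_sample_degs, genes) {
  genes <- as.character(genes)
  unknown <- setdiff(unique(unlist(per_sample_degs)), genes)
  if (length(unknown)) stop("unknown gene id in DEG set: ", unknown[1])
  m <- vapply(per_sample_degs, function(set)
    as.integer(genes %in% set), integer(length(genes)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(genes))
  dimnames(m) <- list(genes, names(per_sample_degs))
  m
}

#' Consensus DEG selection by a permutation test on DEG frequency
#'
#' A gene's DEG frequency is its row sum in the gene x sample DEG matrix.
#' The null distribution is obtained by globally shuffling all matrix
#' entries (preserving the total number of 1s) `n_permutations` times and
#' pooling the per-gene row sums of every shuffled matrix; rows are
#' exchangeable under the global shuffle, so pooled row sums form one null.
#' The permutation p-value uses the +1 correction and is never exactly 0;
#' BH correction is applied across genes.  Each permutation is re-seeded
#' from `seed` alone, so results are invariant to row order of the input.
#'
#' @param deg_matrix Binary matrix from [build_deg_matrix()].
#' @param n_permutations Number of global shuffles (>= 100).
#' @param seed Integer seed (mandatory; every permutation uses
#'   `seed + permutation index`).
#' @param alpha BH-adjusted significance level for consensus membership.
#' @return A `consensus_deg_result`: list with `deg_matrix`, `frequency`,
#'   `p_value`, `adj_p`, `consensus_genes`, `null_counts`, and the
#'   parameters used.
#' @export
consensus_test <- function(deg_matrix, n_permutations = 1000, seed,
                           alpha = 0.05) {
  if (missing(seed)) stop("`seed` is mandatory for the permutation test")
  if (n_permutations < 100) stop("`n_permutations` must be >= 100")
  if (!all(deg_matrix %in% c(0L, 1L))) stop("DEG matrix must be binary")
  genes <- rownames(deg_matrix)
  n_genes <- nrow(deg_matrix); m <- ncol(deg_matrix)
  freq <- rowSums(deg_matrix)
  n_ones <- sum(deg_matrix)
  n_cells <- n_genes * m
  null_counts <- integer(m + 1L)  # null_counts[f+1] = #{null row sums == f}
  for (b in seq_len(n_permutations)) {
    set.seed(seed + b)
    # A global entry shuffle places the 1s on a uniform random cell subset;
    # sampling that subset directly keeps the null a function of the matrix
    # dimensions and the total 1 count only (hence row-order invariant).
    pos <- sample.int(n_cells, n_ones)
    rs <- tabulate((pos - 1L) %% n_genes + 1L, nbins = n_genes)
    null_counts <- null_counts + tabulate(rs + 1L, nbins = m + 1L)
  }
  n_null <- n_permutations * n_genes
  count_ge <- rev(cumsum(rev(null_counts)))  # count_ge[f+1] = #{null >= f}
  p <- (1 + count_ge[freq + 1L]) / (1 + n_null)
  adj <- stats::p.adjust(p, method = "BH")
  names(p) <- names(adj) <- names(freq) <- genes
  structure(
    list(deg_matrix = deg_matrix, frequency = freq, p_value = p,
         adj_p = adj, consensus_genes = genes[adj < alpha],
         null_counts = null_counts, n_permutations = n_permutations,
         alpha = alpha, seed = seed),
    class = "consensus_deg_result")
}

#' @export
print.consensus_deg_result <- function(x, ...) {
  cat(sprintf(
    "<consensus_deg_result> %d genes x %d samples; %d consensus DEGs (adj.p < %g, %d permutations)\n",
    nrow(x$deg_matrix), ncol(x$deg_matrix), length(x$consensus_genes),
    x$alpha, x$n_permutations))
  invisible(x)
}
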