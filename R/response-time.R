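#' Pre/post expression split for a response-time vector
#'
#' Given a response-time vector `rt` (one 1-based time index per sample,
#' each within `[2, l_i]`), pools the gene's replicate values at indices
#' strictly before `rt[i]` into the pre-set and at indices `>= rt[i]` into
#' the post-set, across all samples.  The response time itself belongs to
#' the post-set.
#'
#' @param dataset An [expression_dataset()].
#' @param gene Gene id.
#' @param rt Integer vector, one entry per sample in dataset order.
#' @return List with numeric vectors `pre` and `post`.  Errors with
#'   `"unsplittable"` when either side has fewer than 2 values.
#' @export
split_sets <- function(dataset, gene, rt) {
  check_rt(dataset, rt)
  pre <- c(); post <- c()
  ids <- sample_ids(dataset)
  for (i in seq_along(ids)) {
    l <- length(dataset$design[[ids[i]]]$time_points)
    pre <- c(pre, gene_values(dataset, gene, ids[i], seq_len(rt[i] - 1L)))
    post <- c(post, gene_values(dataset, gene, ids[i], rt[i]:l))
  }
  if (length(pre) < 2L || length(post) < 2L)
    stop("unsplittable: fewer than 2 values on one side of the response time")
  list(pre = pre, post = post)
}

check_rt <- function(dataset, rt) {
  ids <- sample_ids(dataset)
  if (length(rt) != length(ids))
    stop("response-time vector length must equal the number of samples")
  l <- vapply(dataset$design, function(d) length(d$time_points), integer(1))
  if (any(rt < 2L) || any(rt > l))
    stop("response-time indices must lie in [2, l_i]")
  invisible(TRUE)
}

#' Quality score of a gene for a response-time vector
#'
#' The absolute pooled-variance t statistic between the post- and pre-sets
#' of [split_sets()].  With `per_sample = TRUE`, a t statistic is computed
#' within each sample whose own split leaves >= 2 values on both sides and
#' the absolute values are averaged (an alternative reading of the pooled
#' construction).
#'
#' @inheritParams split_sets
#' @param variance_floor Pooled-variance floor (see [two_sample_tstat()]).
#' @param per_sample Average per-sample |t| instead of pooling values.
#' @return Non-negative quality score.
#' @export
gene_tstat <- function(dataset, gene, rt, variance_floor = 1e-8,
                       per_sample = FALSE) {
  if (!per_sample) {
    ss <- split_sets(dataset, gene, rt)
    return(abs(two_sample_tstat(ss$post, ss$pre, variance_floor)))
  }
  check_rt(dataset, rt)
  ids <- sample_ids(dataset)
  ts <- c()
  for (i in seq_along(ids)) {
    l <- length(dataset$design[[ids[i]]]$time_points)
    pre <- gene_values(dataset, gene, ids[i], seq_len(rt[i] - 1L))
    post <- gene_values(dataset, gene, ids[i], rt[i]:l)
    if (length(pre) >= 2L && length(post) >= 2L)
      ts <- c(ts, abs(two_sample_tstat(post, pre, variance_floor)))
  }
  if (length(ts) == 0L)
    stop("unsplittable: no sample has 2 values on both sides")
  mean(ts)
}

#' Quality score of a cluster: mean gene score
#'
#' @inheritParams gene_tstat
#' @param genes Character vector of cluster member gene ids.
#' @return Mean of [gene_tstat()] over the members.
#' @export
cluster_tstat <- function(dataset, genes, rt, variance_floor = 1e-8,
                          per_sample = FALSE) {
  if (length(genes) == 0L) stop("empty cluster")
  mean(vapply(genes, function(g)
    gene_tstat(dataset, g, rt, variance_floor, per_sample), numeric(1)))
}

#' Initial response-time vector by adjacency-constrained segmentation
#'
#' Per sample, each time index is represented by the vector of cluster-
#' member mean expressions at that index.  Adjacent segments are merged
#' agglomeratively — always the adjacent pair whose centroids (means of the
#' original time-point vectors) are closest in Euclidean distance, leftmost
#' pair on ties — until two segments remain.  The initial response time is
#' the first index of the right segment (always >= 2 by construction).
#'
#' @param dataset A normalized [expression_dataset()].
#' @param genes Cluster member gene ids.
#' @return Named integer vector of initial response times, one per sample.
#' @export
init_rt <- function(dataset, genes) {
  ids <- sample_ids(dataset)
  rt <- integer(length(ids))
  for (i in seq_along(ids)) {
    M <- replicate_mean_matrix(dataset, ids[i])[genes, , drop = FALSE]
    l <- ncol(M)
    if (l == 2L) { rt[i] <- 2L; next }
    start <- as.list(seq_len(l))          # members of each segment
    repeat {
      if (length(start) == 2L) break
      cent <- vapply(start, function(jj)
        rowMeans(M[, jj, drop = FALSE]), numeric(nrow(M)))
      if (is.null(dim(cent))) cent <- matrix(cent, nrow = 1L)
      d <- sqrt(colSums((cent[, -1, drop = FALSE] -
                         cent[, -ncol(cent), drop = FALSE])^2))
      j <- which.min(d)                   # leftmost minimum
      start[[j]] <- c(start[[j]], start[[j + 1L]])
      start[[j + 1L]] <- NULL
    }
    rt[i] <- max(2L, min(start[[2L]]))
  }
  names(rt) <- ids
  rt
}

#' Hill-climbing search for the cluster response-time vector
#'
#' Starting from `init`, repeatedly scores every vector obtained by moving
#' one sample's response time by up to `move_radius` indices (staying in
#' `[2, l_i]`) with [cluster_tstat()], and moves to the best candidate if it
#' improves the current score by more than `tol`; stops otherwise.
#' Candidates whose split is degenerate score `-Inf`.  Ties among best
#' candidates are resolved by sample index (ascending), then earlier time.
#'
#' @inheritParams cluster_tstat
#' @param init Starting response-time vector (e.g. from [init_rt()]).
#' @param move_radius Neighborhood radius in time indices (default 1).
#' @param tol Minimal score improvement to accept a move.
#' @return List with `rt` (final vector), `score` and `n_moves`.
#' @export
hill_climb_rt <- function(dataset, genes, init, move_radius = 1, tol = 1e-9,
                          variance_floor = 1e-8, per_sample = FALSE) {
  check_rt(dataset, init)
  score <- function(rt) tryCatch(
    cluster_tstat(dataset, genes, rt, variance_floor, per_sample),
    error = function(e) -Inf)
  l <- vapply(dataset$design, function(d) length(d$time_points), integer(1))
  cur <- as.integer(init); names(cur) <- names(init)
  cur_score <- score(cur)
  n_moves <- 0L
  repeat {
    cand <- list()
    for (i in seq_along(cur)) {
      lo <- max(2L, cur[i] - move_radius)
      hi <- min(l[i], cur[i] + move_radius)
      for (t in lo:hi) {
        if (t == cur[i]) next
        nxt <- cur; nxt[i] <- t
        cand[[length(cand) + 1L]] <- nxt
      }
    }
    if (length(cand) == 0L) break
    scores <- vapply(cand, score, numeric(1))
    b <- which.max(scores)                # first max: sample asc, time asc
    if (!(scores[b] > cur_score + tol)) break
    cur <- cand[[b]]; cur_score <- scores[b]
    n_moves <- n_moves + 1L
    if (n_moves > 10000L) stop("hill climbing failed to terminate")
  }
  list(rt = cur, score = cur_score, n_moves = n_moves)
}
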