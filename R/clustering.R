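#' Concatenated multi-sample expression profiles
#'
#' Builds, for each gene, the concatenation (over samples, in the dataset's
#' sample order) of replicate-averaged expression across that sample's time
#' points.  The resulting vectors, of length `sum(l_i)`, are the objects
#' clustered by [spherical_kmeans()].  Genes whose profile is exactly zero
#' everywhere are excluded with a warning (cosine direction undefined).
#'
#' @param dataset A base-normalized [expression_dataset()].
#' @param genes Genes to profile (subset of the dataset's genes).
#' @return Numeric matrix, one row per retained gene.
#' @export
build_profiles <- function(dataset, genes) {
  genes <- as.character(genes)
  if (!all(genes %in% dataset$genes))
    stop("unknown gene id: ", setdiff(genes, dataset$genes)[1])
  blocks <- lapply(sample_ids(dataset), function(s)
    replicate_mean_matrix(dataset, s)[genes, , drop = FALSE])
  x <- do.call(cbind, blocks)
  rownames(x) <- genes
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) {
    warning(sprintf("excluding %d all-zero gene profile(s)", sum(nrm == 0)))
    x <- x[nrm > 0, , drop = FALSE]
  }
  x
}

#' Spherical k-means clustering of gene profiles
#'
#' Rows are L2-normalized and partitioned by alternating assignment
#' (maximum dot product, i.e. cosine similarity, with the centroids) and
#' centroid update (normalized mean of members).  Initialization is
#' k-means++ on the unit sphere using cosine distance weights; the best of
#' `n_restarts` runs (highest total cosine similarity) is returned.  A
#' cluster emptied during iteration is re-seeded with the profile farthest
#' (lowest maximum similarity) from all current centroids.
#'
#' @param profiles Matrix from [build_profiles()] (rows = genes).
#' @param k Number of clusters (2 <= k <= nrow(profiles)).
#' @param seed Integer seed; restart `r` uses `seed + r - 1`.
#' @param n_restarts Number of random restarts.
#' @param max_iter Iteration cap per restart.
#' @return List of `gene_cluster` objects: `cluster_id`, `members`
#'   (gene ids), `centroid` (unit vector), `quality` and `rt` (filled
#'   later by the response-time step).
#' @export
spherical_kmeans <- function(profiles, k, seed, n_restarts = 10,
                             max_iter = 100) {
  if (missing(seed)) stop("`seed` is mandatory")
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be >= 2")
  if (nrow(profiles) < k) stop("fewer profiles than clusters")
  x <- profiles / sqrt(rowSums(profiles^2))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    fit <- .skmeans_once(x, k, max_iter)
    if (is.null(best) || fit$objective > best$objective) best <- fit
  }
  clusters <- vector("list", k)
  for (i in seq_len(k)) {
    members <- rownames(x)[best$assignment == i]
    clusters[[i]] <- structure(
      list(cluster_id = i, members = members, size = length(members),
           centroid = best$centroids[i, ], quality = NULL, rt = NULL),
      class = "gene_cluster")
  }
  attr(clusters, "objective") <- best$objective
  clusters
}

.skmeans_once <- function(x, k, max_iter) {
  n <- nrow(x)
  # k-means++ seeding with cosine distance (1 - similarity) weights.
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  dmin <- pmax(0, 1 - drop(x %*% x[centers[1], ]))
  for (i in seq_len(k - 1L) + 1L) {
    w <- dmin
    w[centers[seq_len(i - 1L)]] <- 0
    centers[i] <- if (sum(w) > 0) sample.int(n, 1, prob = w)
                  else sample(setdiff(seq_len(n), centers[seq_len(i - 1L)]), 1)
    dmin <- pmin(dmin, pmax(0, 1 - drop(x %*% x[centers[i], ])))
  }
  C <- x[centers, , drop = FALSE]
  assign_prev <- rep(0L, n)
  for (iter in seq_len(max_iter)) {
    S <- x %*% t(C)                       # n x k cosine similarities
    a <- max.col(S, ties.method = "first")
    best_sim <- S[cbind(seq_len(n), a)]
    for (j in which(tabulate(a, k) == 0L)) {   # re-seed empty clusters
      far <- which.min(best_sim)
      a[far] <- j
      best_sim[far] <- 1  # cannot be stolen by another empty cluster
    }
    if (identical(a, assign_prev)) break
    assign_prev <- a
    for (j in seq_len(k)) {
      mu <- colSums(x[a == j, , drop = FALSE])
      nm <- sqrt(sum(mu^2))
      if (nm > 0) C[j, ] <- mu / nm
    }
  }
  S <- x %*% t(C)
  a <- max.col(S, ties.method = "first")
  list(assignment = a, centroids = C,
       objective = sum(S[cbind(seq_len(n), a)]))
}

#' @export
print.gene_cluster <- function(x, ...) {
  cat(sprintf("<gene_cluster %d> %d genes%s%s\n", x$cluster_id, x$size,
              if (!is.null(x$quality)) sprintf(", Tstat %.3f", x$quality) else "",
              if (!is.null(x$rt)) sprintf(", RT <%s>",
                                          paste(x$rt, collapse = ",")) else ""))
  invisible(x)
}

#' Discard clusters with fewer than `min_size` members
#'
#' Small clusters carry too little signal for a stable response time; the
#' survivors are re-indexed 1..n in their original order.
#'
#' @param clusters List of `gene_cluster` objects.
#' @param min_size Minimum membership (default 3).
#' @return Filtered, re-indexed cluster list.
#' @export
filter_small_clusters <- function(clusters, min_size = 3) {
  keep <- Filter(function(cl) cl$size >= min_size, clusters)
  if (length(keep) == 0L)
    stop("no usable clusters: all have fewer than ", min_size, " members")
  for (i in seq_along(keep)) keep[[i]]$cluster_id <- i
  keep
}

#' Choose the number of clusters by F1 against top-ranked consensus DEGs
#'
#' Runs the clustering / response-time / scheduling stages for every `k` in
#' `k_grid` and scores the final response-order-preserving gene set against
#' a proxy truth: the top 10% of consensus DEGs ranked by permutation
#' p-value (ascending), then DEG frequency (descending), then gene id.
#' Returns the `k` maximizing the F1 score; ties go to the smaller `k`.
#'
#' @param dataset Normalized [expression_dataset()].
#' @param consensus A `consensus_deg_result`.
#' @param k_grid Candidate cluster counts.
#' @param seed Integer seed passed to the clustering stage.
#' @param ... Further arguments forwarded to the pipeline stages (see
#'   [run_pipeline()]).
#' @return Selected `k` (integer), with the per-`k` F1 table in the
#'   `"f1_table"` attribute.
#' @export
select_k <- function(dataset, consensus, k_grid, seed, ...) {
  if (length(k_grid) == 0L) stop("`k_grid` must be non-empty")
  genes <- consensus$consensus_genes
  ord <- order(consensus$p_value[genes], -consensus$frequency[genes], genes)
  n_top <- max(1L, floor(0.1 * length(genes)))
  proxy <- genes[ord][seq_len(n_top)]
  k_grid <- sort(unique(as.integer(k_grid)))
  f1 <- rep(NA_real_, length(k_grid))
  for (i in seq_along(k_grid)) {
    res <- tryCatch(
      cluster_and_schedule(dataset, genes, k = k_grid[i], seed = seed, ...),
      error = function(e) NULL)
    found <- if (is.null(res)) character() else res$result$gene_id
    f1[i] <- f1_score(found, proxy)
  }
  if (all(is.na(f1))) stop("no k in `k_grid` produced a usable clustering")
  best <- k_grid[which.max(f1)]   # which.max takes the first (smallest k) tie
  structure(best, f1_table = data.frame(k = k_grid, f1 = f1))
}

f1_score <- function(found, truth) {
  tp <- length(intersect(found, truth))
  if (length(found) == 0L || length(truth) == 0L || tp == 0L) return(0)
  prec <- tp / length(found)
  rec <- tp / length(truth)
  2 * prec * rec / (prec + rec)
}
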