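# Fixture builders and independent oracles shared across the test files.

# Dataset from a list of per-sample mean matrices (genes x time); every
# time point gets `n_rep` identical replicates plus optional jitter.
toy_dataset <- function(mats, n_rep = 1, time_points = NULL, jitter = 0) {
  genes <- rownames(mats[[1]])
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(mats[[1]])))
  design <- list(); values <- list()
  for (i in seq_along(mats)) {
    sid <- names(mats)[i]
    if (is.null(sid) || sid == "") sid <- paste0("s", i)
    l <- ncol(mats[[i]])
    tp <- if (is.null(time_points)) 0:(l - 1) else time_points[[i]]
    design[[sid]] <- sample_design(sid, tp, n_rep)
    arr <- array(NA_real_, dim = c(length(genes), l, n_rep))
    for (k in seq_len(n_rep))
      arr[, , k] <- mats[[i]] +
        if (jitter > 0) matrix(stats::rnorm(length(genes) * l, sd = jitter),
                               length(genes)) else 0
    values[[sid]] <- arr
  }
  expression_dataset(genes, design, values)
}

# Single-sample dataset from a genes x time matrix.
series_dataset <- function(mat, n_rep = 1, ...) {
  toy_dataset(list(s1 = mat), n_rep = n_rep, ...)
}

# Independent oracle for the response-time search: exhaustive enumeration
# of every response-time vector on the full grid.
exhaustive_rt <- function(dataset, genes, variance_floor = 1e-8) {
  l <- vapply(dataset$design, function(d) length(d$time_points), integer(1))
  grid <- do.call(expand.grid, lapply(l, function(li) 2:li))
  best <- -Inf; best_rt <- NULL
  for (r in seq_len(nrow(grid))) {
    rt <- as.integer(grid[r, ])
    sc <- tryCatch(cluster_tstat(dataset, genes, rt, variance_floor),
                   error = function(e) -Inf)
    if (sc > best) { best <- sc; best_rt <- rt }
  }
  list(rt = best_rt, score = best)
}

# Independent oracle for scheduling: brute-force maximum pairwise
# conflict-free subset over all 2^n subsets of response-time vectors.
brute_max_conflict_free <- function(rts) {
  n <- nrow(rts)
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    ix <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(ix) <= best) next
    ok <- TRUE
    if (length(ix) > 1) {
      for (a in seq_along(ix)[-1]) for (b in seq_len(a - 1)) {
        if (rt_precedes(rts[ix[a], ], rts[ix[b], ]) == "conflict") {
          ok <- FALSE; break
        }
      }
    }
    if (ok) best <- length(ix)
  }
  best
}

# Random small step-signal cluster instance for the RT oracle tests.
random_step_instance <- function(seed) {
  set.seed(seed)
  m <- sample(1:2, 1)
  l <- sample(3:5, m, replace = TRUE)
  n_genes <- sample(3:5, 1)
  change <- vapply(l, function(li) sample(2:li, 1), integer(1))
  sign <- sample(c(-1, 1), n_genes, replace = TRUE)
  mats <- lapply(seq_len(m), function(i) {
    mu <- outer(sign * 4, as.numeric(seq_len(l[i]) >= change[i]))
    mu + matrix(stats::rnorm(n_genes * l[i], sd = 0.3), n_genes)
  })
  names(mats) <- paste0("s", seq_len(m))
  list(dataset = toy_dataset(mats, n_rep = 2, jitter = 0.1),
       change = change)
}
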