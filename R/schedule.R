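#' Order relation between two response-time vectors
#'
#' Vector `r1` precedes `r2` when `r1 <= r2` in every sample with strict
#' inequality in at least one; the symmetric case is `"after"`; identical
#' vectors are `"equal"`; vectors whose elements disagree in order (one
#' earlier in some sample, later in another) `"conflict"` and cannot be
#' placed on a common response schedule.
#'
#' @param r1,r2 Integer response-time vectors of equal length.
#' @return One of `"before"`, `"after"`, `"equal"`, `"conflict"`.
#' @export
#' @examples
#' rt_precedes(c(1, 2, 3, 4), c(1, 3, 2, 4))  # "conflict"
rt_precedes <- function(r1, r2) {
  if (length(r1) != length(r2))
    stop("response-time vectors have different lengths")
  d <- r2 - r1
  if (all(d == 0)) return("equal")
  if (all(d >= 0)) return("before")
  if (all(d <= 0)) return("after")
  "conflict"
}

#' Build the response schedule from scored clusters
#'
#' Greedy construction: clusters are considered in decreasing quality-score
#' order (ties: larger membership, then smaller cluster id).  A cluster is
#' added if its response-time vector does not conflict with any cluster
#' already in the schedule, and discarded otherwise.  Scheduled clusters
#' are then sorted by the partial order and assigned 1-based response
#' phases; clusters with identical vectors share a phase.
#'
#' With `exact = TRUE` the greedy scan is replaced by dynamic programming
#' for a maximum-size conflict-free subset (longest chain over the
#' dominance order of distinct vectors, weighted by the number of clusters
#' sharing each vector); intended for small cluster counts.
#'
#' @param clusters List of `gene_cluster` objects with `rt` and `quality`
#'   filled (see [hill_climb_rt()]).
#' @param exact Use the exact longest-chain construction instead of the
#'   greedy scan.
#' @return A `response_schedule`: list with `entries` (data frame of
#'   cluster_id, phase, quality, size), `rt` (matrix of scheduled vectors,
#'   one row per cluster) and `phases` (named by cluster id).
#' @export
build_schedule <- function(clusters, exact = FALSE) {
  if (length(clusters) == 0L)
    return(structure(list(entries = data.frame(cluster_id = integer(),
                                               phase = integer(),
                                               quality = numeric(),
                                               size = integer()),
                          rt = NULL, phases = integer()),
                     class = "response_schedule"))
  for (cl in clusters)
    if (is.null(cl$rt) || is.null(cl$quality))
      stop("all clusters need `rt` and `quality` before scheduling")
  rts <- do.call(rbind, lapply(clusters, `[[`, "rt"))
  qual <- vapply(clusters, `[[`, numeric(1), "quality")
  size <- vapply(clusters, `[[`, numeric(1), "size")
  ids <- vapply(clusters, `[[`, numeric(1), "cluster_id")

  kept <- if (exact) .longest_chain(rts, qual) else {
    ord <- order(-qual, -size, ids)
    acc <- integer()
    for (i in ord) {
      conflict <- any(vapply(acc, function(j)
        rt_precedes(rts[i, ], rts[j, ]) == "conflict", logical(1)))
      if (!conflict) acc <- c(acc, i)
    }
    acc
  }

  # Comparable pairwise, so row sums order the kept vectors consistently.
  kept <- kept[order(rowSums(rts[kept, , drop = FALSE]), ids[kept])]
  key <- apply(rts[kept, , drop = FALSE], 1, paste, collapse = ",")
  phase <- cumsum(!duplicated(key))
  entries <- data.frame(cluster_id = as.integer(ids[kept]), phase = phase,
                        quality = qual[kept], size = as.integer(size[kept]))
  rt <- rts[kept, , drop = FALSE]
  rownames(rt) <- entries$cluster_id
  structure(list(entries = entries, rt = rt,
                 phases = stats::setNames(phase, entries$cluster_id)),
            class = "response_schedule")
}

# Maximum-weight chain over the dominance order of distinct RT vectors;
# weight of a vector = number of clusters carrying it (all clusters with
# equal vectors are mutually compatible).  Returns cluster row indices.
.longest_chain <- function(rts, qual) {
  key <- apply(rts, 1, paste, collapse = ",")
  groups <- split(seq_len(nrow(rts)), key)
  grts <- do.call(rbind, lapply(groups, function(ix) rts[ix[1], ]))
  w <- vapply(groups, length, integer(1))
  g <- length(groups)
  ord <- order(rowSums(grts))             # topological for the dominance DAG
  best <- w[ord]; prev <- rep(NA_integer_, g)
  for (a in seq_len(g)) {
    for (b in seq_len(a - 1L)) {
      if (rt_precedes(grts[ord[b], ], grts[ord[a], ]) %in% c("before", "equal") &&
          best[b] + w[ord[a]] > best[a]) {
        best[a] <- best[b] + w[ord[a]]
        prev[a] <- b
      }
    }
  }
  end <- which.max(best)
  chain <- integer()
  while (!is.na(end)) { chain <- c(ord[end], chain); end <- prev[end] }
  unlist(groups[chain], use.names = FALSE)
}

#' @export
print.response_schedule <- function(x, ...) {
  cat(sprintf("<response_schedule> %d cluster(s), %d phase(s)\n",
              nrow(x$entries),
              if (nrow(x$entries)) max(x$entries$phase) else 0L))
  invisible(x)
}

#' Collect scheduled genes into a result table
#'
#' One row per member gene of every scheduled cluster, carrying its cluster
#' id, response phase and the cluster's per-sample response-time indices.
#'
#' @param schedule A `response_schedule` from [build_schedule()].
#' @param clusters The full cluster list the schedule was built from.
#' @param sample_names Sample ids naming the `rt_` columns.
#' @return A [result_table()].
#' @export
collect_result <- function(schedule, clusters, sample_names) {
  rt_cols <- paste0("rt_", sample_names)
  empty <- as.data.frame(stats::setNames(
    c(list(character(), integer(), integer()),
      replicate(length(rt_cols), integer(), simplify = FALSE)),
    c("gene_id", "cluster_id", "phase", rt_cols)))
  if (nrow(schedule$entries) == 0L) {
    return(result_table(empty, clusters = data.frame(
      cluster_id = integer(), size = integer(), tstat = numeric(),
      phase = integer())))
  }
  by_id <- stats::setNames(clusters,
                           vapply(clusters, `[[`, numeric(1), "cluster_id"))
  rows <- list(); crows <- list()
  for (i in seq_len(nrow(schedule$entries))) {
    e <- schedule$entries[i, ]
    cl <- by_id[[as.character(e$cluster_id)]]
    rt <- schedule$rt[i, ]
    rdf <- data.frame(gene_id = cl$members, cluster_id = e$cluster_id,
                      phase = e$phase, stringsAsFactors = FALSE)
    rdf[rt_cols] <- rep(as.list(as.integer(rt)), each = 1L)
    rows[[i]] <- rdf
    cdf <- data.frame(cluster_id = e$cluster_id, size = cl$size,
                      tstat = e$quality, phase = e$phase)
    cdf[rt_cols] <- as.list(as.integer(rt))
    crows[[i]] <- cdf
  }
  result_table(do.call(rbind, rows), clusters = do.call(rbind, crows))
}
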