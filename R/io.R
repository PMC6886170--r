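#' Read an expression dataset from long-format TSV
#'
#' The canonical exchange format is a long table with columns
#' `gene, sample, time, replicate, value` plus a design table with columns
#' `sample, time, n_replicates` (one row per sample/time point).  Row order
#' is irrelevant; the result depends only on the content.
#'
#' @param expression_table Path to the long-format expression TSV.
#' @param design_table Path to the design TSV.
#' @param intersect_genes When samples carry different gene sets, keep the
#'   intersection (default) instead of failing.  Genes absent from any
#'   sample are dropped with a warning.
#' @return An [expression_dataset()].
#' @export
read_dataset <- function(expression_table, design_table, intersect_genes = TRUE) {
  des <- utils::read.delim(design_table, colClasses = "character",
                           check.names = FALSE)
  need <- c("sample", "time", "n_replicates")
  if (!all(need %in% names(des)))
    stop("design table must have columns: ", paste(need, collapse = ", "))
  des$time <- as.numeric(des$time)
  des$n_replicates <- as.integer(des$n_replicates)
  design <- lapply(split(des, des$sample), function(d) {
    d <- d[order(d$time), ]
    sample_design(d$sample[1], d$time, d$n_replicates)
  })
  design <- design[unique(des$sample)]

  tab <- utils::read.delim(expression_table, colClasses = "character",
                           check.names = FALSE)
  need <- c("gene", "sample", "time", "replicate", "value")
  if (!all(need %in% names(tab)))
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  val <- suppressWarnings(as.numeric(tab$value))
  bad <- which(is.na(val) & !(tab$value %in% c("NA", "")))
  if (length(bad))
    stop(sprintf("non-numeric value '%s' at line %d of %s",
                 tab$value[bad[1]], bad[1] + 1L, expression_table))
  if (anyNA(val))
    stop(sprintf("missing value at line %d of %s",
                 which(is.na(val))[1] + 1L, expression_table))
  tim <- suppressWarnings(as.numeric(tab$time))
  if (anyNA(tim))
    stop(sprintf("non-numeric time at line %d of %s",
                 which(is.na(tim))[1] + 1L, expression_table))

  if (!all(tab$sample %in% names(design)))
    stop("expression table references sample absent from design table: ",
         setdiff(tab$sample, names(design))[1])

  key <- paste(tab$gene, tab$sample, tim, tab$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    d <- tab[which(duplicated(key))[1], ]
    stop(sprintf(
      "duplicate record for gene '%s', sample '%s', time %s, replicate '%s'",
      d$gene, d$sample, d$time, d$replicate))
  }

  # Gene universe: identical across samples unless intersecting.
  per_sample_genes <- lapply(split(tab$gene, tab$sample), unique)
  genes <- sort(unique(tab$gene))
  common <- Reduce(intersect, per_sample_genes)
  if (length(common) < length(genes)) {
    if (!intersect_genes)
      stop("gene universe differs across samples; set intersect_genes = TRUE ",
           "to keep the intersection")
    warning(sprintf("dropping %d gene(s) absent from some sample",
                    length(genes) - length(common)))
    keep <- tab$gene %in% common
    tab <- tab[keep, ]; val <- val[keep]; tim <- tim[keep]
    genes <- sort(common)
  }
  if (length(genes) == 0L) stop("no genes shared across all samples")

  values <- list()
  for (s in names(design)) {
    d <- design[[s]]
    rows <- tab$sample == s
    jj <- match(tim[rows], d$time_points)
    if (anyNA(jj))
      stop(sprintf("sample '%s' has a measurement at time %s not in the design",
                   s, tim[rows][which(is.na(jj))[1]]))
    sub <- data.frame(gene = tab$gene[rows], j = jj,
                      replicate = tab$replicate[rows], value = val[rows],
                      stringsAsFactors = FALSE)
    arr <- array(NA_real_, dim = c(length(genes), length(d$time_points),
                                   max(d$n_replicates)))
    for (j in seq_along(d$time_points)) {
      sj <- sub[sub$j == j, ]
      cnt <- table(factor(sj$gene, levels = genes))
      if (any(cnt == 0L))
        stop(sprintf(
          "incomplete design: no value for gene '%s', sample '%s', time %g",
          genes[which(cnt == 0L)[1]], s, d$time_points[j]))
      if (any(cnt != d$n_replicates[j]))
        stop(sprintf(
          "replicate count mismatch for gene '%s', sample '%s', time %g (found %d, design says %d)",
          genes[which(cnt != d$n_replicates[j])[1]], s, d$time_points[j],
          max(cnt), d$n_replicates[j]))
      # Replicate slot = rank of the replicate label within (sample, time).
      sj <- sj[order(sj$gene, sj$replicate), ]
      k <- stats::ave(seq_len(nrow(sj)), sj$gene, FUN = seq_along)
      arr[cbind(match(sj$gene, genes), j, k)] <- sj$value
    }
    values[[s]] <- arr
  }
  expression_dataset(genes, design, values)
}

#' Write an expression dataset as the long-format TSV pair
#'
#' Inverse of [read_dataset()]: emits the expression table and design table
#' so that reading them back reproduces the dataset.
#'
#' @param dataset An [expression_dataset()].
#' @param expression_table,design_table Output paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_dataset <- function(dataset, expression_table, design_table) {
  rows <- lapply(sample_ids(dataset), function(s) {
    d <- dataset$design[[s]]
    v <- dataset$values[[s]]
    out <- list()
    for (j in seq_along(d$time_points)) {
      for (k in seq_len(d$n_replicates[j])) {
        out[[length(out) + 1L]] <- data.frame(
          gene = dataset$genes, sample = s, time = d$time_points[j],
          replicate = k, value = v[, j, k], stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, expression_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  des <- do.call(rbind, lapply(dataset$design, function(d) {
    data.frame(sample = d$sample_id, time = d$time_points,
               n_replicates = d$n_replicates, stringsAsFactors = FALSE)
  }))
  utils::write.table(des, design_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expression_table, design_table))
}

#' Result table of response-order-preserving genes
#'
#' One row per retained gene, with its cluster, response phase and the
#' cluster's per-sample response-time indices (columns `rt_<sample>`).
#' A companion cluster-level table (size, quality score, phase, response
#' times) is carried in the `"clusters"` attribute.
#'
#' @param df Data frame with columns `gene_id`, `cluster_id`, `phase` and
#'   one `rt_<sample>` column per sample.
#' @param clusters Cluster-level data frame (may be empty).
#' @return A `result_table` (a data frame subclass).
#' @export
result_table <- function(df, clusters = NULL) {
  need <- c("gene_id", "cluster_id", "phase")
  if (!all(need %in% names(df)))
    stop("result table needs columns: ", paste(need, collapse = ", "))
  if (nrow(df) > 0 && any(df$phase < 1L)) stop("phase indices must be >= 1")
  df$gene_id <- as.character(df$gene_id)
  df$cluster_id <- as.integer(df$cluster_id)
  df$phase <- as.integer(df$phase)
  rownames(df) <- NULL
  structure(df, clusters = clusters, class = c("result_table", "data.frame"))
}

rt_columns <- function(df) grep("^rt_", names(df), value = TRUE)

#' Write analysis results to a directory
#'
#' Writes `genes.tsv` (one row per response-order-preserving gene) and
#' `clusters.tsv` (cluster id, size, quality score, response-time vector and
#' phase, sorted by phase then cluster id).  Both files round-trip through
#' [read_results()].
#'
#' @param result A [result_table()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(result, out_dir) {
  stopifnot(inherits(result, "result_table"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  gene_path <- file.path(out_dir, "genes.tsv")
  clus_path <- file.path(out_dir, "clusters.tsv")
  gdf <- as.data.frame(result)
  gdf <- gdf[order(gdf$phase, gdf$cluster_id, gdf$gene_id), , drop = FALSE]
  utils::write.table(gdf, gene_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cdf <- attr(result, "clusters")
  if (is.null(cdf))
    cdf <- data.frame(cluster_id = integer(), size = integer(),
                      tstat = numeric(), phase = integer())
  if (nrow(cdf) > 0)
    cdf <- cdf[order(cdf$phase, cdf$cluster_id), , drop = FALSE]
  utils::write.table(cdf, clus_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(gene_path, clus_path))
}

#' Read results back from a directory
#'
#' @param out_dir Directory previously written by [write_results()].
#' @return A [result_table()].
#' @export
read_results <- function(out_dir) {
  gdf <- utils::read.delim(file.path(out_dir, "genes.tsv"),
                           colClasses = NA, check.names = FALSE)
  cdf <- utils::read.delim(file.path(out_dir, "clusters.tsv"),
                           colClasses = NA, check.names = FALSE)
  if (nrow(gdf) > 0) gdf$gene_id <- as.character(gdf$gene_id)
  else gdf$gene_id <- character()
  result_table(gdf, clusters = cdf)
}

# Flat key: value manifest, one entry per line.
write_manifest <- function(params, path) {
  lines <- vapply(names(params), function(k)
    sprintf("%s: %s", k, paste(params[[k]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key:value run configuration file
#'
#' Lines of the form `key: value`; blank lines and `#` comments ignored.
#' Values are returned as character strings; the caller coerces.
#'
#' @param path Path to the configuration file.
#' @return Named list of character values.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1]])
  stats::setNames(lapply(m, `[[`, 3L), trimws(vapply(m, `[[`, character(1), 2L)))
}
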