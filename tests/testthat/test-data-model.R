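test_that("long-format TSV round-trips through read and write", {
  mats <- list(s1 = matrix(1:12, 2, dimnames = list(c("gA", "gB"), NULL)),
               s2 = matrix(seq(0.5, 4, 0.5), 2))
  ds <- toy_dataset(mats, n_rep = 2, time_points = list(c(0, 1, 3, 6, 12, 24),
                                                        c(0, 2, 8, 24)))
  ex <- tempfile(fileext = ".tsv"); de <- tempfile(fileext = ".tsv")
  write_dataset(ds, ex, de)
  back <- read_dataset(ex, de)
  expect_equal(back$genes, ds$genes)
  expect_equal(back$design, ds$design)
  expect_equal(back$values, ds$values, ignore_attr = TRUE)
  d <- back$design$s1
  expect_equal(length(d$time_points), 6)
  expect_equal(d$n_replicates, rep(2L, 6))
})

test_that("reader output is independent of input row order", {
  ds <- toy_dataset(list(s1 = matrix(rnorm(9), 3), s2 = matrix(rnorm(6), 3, 2)),
                    n_rep = 2)
  ex <- tempfile(); de <- tempfile()
  write_dataset(ds, ex, de)
  tab <- read.delim(ex)
  set.seed(4)
  shuf <- tab[sample(nrow(tab)), ]
  ex2 <- tempfile()
  write.table(shuf, ex2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_dataset(ex2, de), read_dataset(ex, de))
})

test_that("reader rejects malformed tables with informative errors", {
  ds <- toy_dataset(list(s1 = matrix(1:6, 2)), n_rep = 1)
  ex <- tempfile(); de <- tempfile()
  write_dataset(ds, ex, de)
  tab <- read.delim(ex)

  drop_one <- tab[-2, ]  # removes a whole (gene, sample, time) cell
  f <- tempfile(); write.table(drop_one, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_dataset(f, de), "incomplete design")

  bad <- tab; bad$value[3] <- "oops"
  f <- tempfile(); write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_dataset(f, de), "line 4")

  dup <- rbind(tab, tab[1, ])
  f <- tempfile(); write.table(dup, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_dataset(f, de), "duplicate")
})

test_that("gene universes are intersected across samples when asked", {
  ds <- toy_dataset(list(s1 = matrix(1:6, 2), s2 = matrix(1:6, 2)), n_rep = 1)
  ex <- tempfile(); de <- tempfile()
  write_dataset(ds, ex, de)
  tab <- read.delim(ex)
  tab <- tab[!(tab$gene == "g2" & tab$sample == "s2"), ]
  f <- tempfile(); write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(back <- read_dataset(f, de), "dropping 1 gene")
  expect_equal(back$genes, "g1")
  expect_error(read_dataset(f, de, intersect_genes = FALSE), "differs")
})

test_that("sample designs validate their invariants", {
  expect_error(sample_design("s", c(0, 0, 1), 2), "strictly increasing")
  expect_error(sample_design("s", 5, 2), "at least 2")
  expect_error(sample_design("s", c(0, 1), 0), "positive")
  d <- sample_design("s", c(0, 2, 4), c(2, 3, 2))
  expect_equal(d$n_replicates, c(2L, 3L, 2L))
})

test_that("result tables round-trip through the output directory", {
  df <- data.frame(gene_id = c("g1", "g2", "g3"),
                   cluster_id = c(1L, 1L, 2L), phase = c(1L, 1L, 2L),
                   rt_s1 = c(2L, 2L, 3L), rt_s2 = c(3L, 3L, 4L))
  cl <- data.frame(cluster_id = c(1L, 2L), size = c(2L, 1L),
                   tstat = c(5.5, 4.25), phase = c(1L, 2L),
                   rt_s1 = c(2L, 3L), rt_s2 = c(3L, 4L))
  res <- result_table(df, clusters = cl)
  dir <- tempfile();
  write_results(res, dir)
  back <- read_results(dir)
  expect_equal(as.data.frame(back), as.data.frame(res), ignore_attr = TRUE)
  expect_equal(attr(back, "clusters"), cl, ignore_attr = TRUE)
  # clusters.tsv sorted by phase then cluster id
  written <- read.delim(file.path(dir, "clusters.tsv"))
  expect_false(is.unsorted(written$phase))
})

test_that("empty result tables write header-only files", {
  empty <- result_table(data.frame(gene_id = character(),
                                   cluster_id = integer(), phase = integer(),
                                   rt_s1 = integer()))
  dir <- tempfile()
  write_results(empty, dir)
  lines <- readLines(file.path(dir, "genes.tsv"))
  expect_length(lines, 1)
  expect_match(lines, "^gene_id\t")
  expect_equal(nrow(read_results(dir)), 0)
})

test_that("dataset constructor rejects inconsistent replicate layouts", {
  arr <- array(1, dim = c(2, 3, 2))
  arr[1, 2, 1] <- NA  # hole inside the declared replicate range
  expect_error(
    expression_dataset(c("g1", "g2"),
                       list(sample_design("s1", c(0, 1, 2), 2)),
                       list(s1 = arr)),
    "incomplete design")
})
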