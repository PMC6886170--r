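test_that("pre/post splits pool values across samples as defined", {
  ds <- series_dataset(matrix(c(0, 0, 5, 5), 1))
  ss <- split_sets(ds, "g1", 3)
  expect_equal(sort(ss$pre), c(0, 0))
  expect_equal(sort(ss$post), c(5, 5))

  ds2 <- toy_dataset(list(s1 = matrix(1:3, 1), s2 = matrix(4:6, 1)))
  ss <- split_sets(ds2, "g1", c(2L, 3L))
  expect_equal(sort(ss$pre), c(1, 4, 5))   # s1 index 1 + s2 indices 1-2
  expect_equal(sort(ss$post), c(2, 3, 6))

  # boundary: rt at l_i leaves only the last index in the post set
  ss <- split_sets(ds2, "g1", c(3L, 3L))
  expect_equal(sort(ss$post), c(3, 6))
})

test_that("degenerate splits and invalid vectors are rejected", {
  ds <- series_dataset(matrix(c(0, 1, 2), 1))
  expect_error(split_sets(ds, "g1", 2), "unsplittable")  # single pre value
  expect_error(split_sets(ds, "g1", 1), "\\[2, l_i\\]")
  expect_error(split_sets(ds, "g1", 4), "\\[2, l_i\\]")
  expect_error(split_sets(ds, "g1", c(2L, 2L)), "length")
})

test_that("gene quality scores match the frozen oracle values", {
  # zero-variance split engages the floor: 5 / sqrt(1e-8 * 1)
  ds <- series_dataset(matrix(c(0, 0, 5, 5), 1))
  expect_equal(gene_tstat(ds, "g1", 3), 5 / sqrt(1e-8))
  # pooled variance (0.005 + 0.005)/2, t = 3.9/sqrt(0.005); cross-checked
  # against t.test(var.equal = TRUE)
  ds <- series_dataset(matrix(c(0, 0.1, 3.9, 4.0), 1))
  expect_equal(gene_tstat(ds, "g1", 3), 55.154, tolerance = 1e-4)
  ref <- t.test(c(3.9, 4.0), c(0, 0.1), var.equal = TRUE)$statistic
  expect_equal(gene_tstat(ds, "g1", 3), unname(abs(ref)), tolerance = 1e-9)
  # identical pre and post multisets score 0
  ds <- series_dataset(matrix(c(1, 2, 1, 2), 1), n_rep = 2)
  expect_equal(gene_tstat(ds, "g1", 3), 0)
})

test_that("cluster quality is the mean of member gene scores", {
  mats <- list(s1 = rbind(g1 = c(0, 0, 4, 4), g2 = c(0, 0, 6, 6)))
  ds <- toy_dataset(mats, n_rep = 2)
  t1 <- gene_tstat(ds, "g1", 3); t2 <- gene_tstat(ds, "g2", 3)
  expect_equal(cluster_tstat(ds, c("g1", "g2"), 3), (t1 + t2) / 2)
  expect_equal(cluster_tstat(ds, "g1", 3), t1)
  expect_error(cluster_tstat(ds, character(), 3), "empty cluster")
})

test_that("gene scores are invariant to sample and replicate order", {
  set.seed(41)
  mats <- list(s1 = matrix(rnorm(8), 2), s2 = matrix(rnorm(10), 2))
  ds <- toy_dataset(mats, n_rep = 2, jitter = 0.3)
  ds_rev <- expression_dataset(ds$genes, rev(ds$design), rev(ds$values))
  rt <- c(2L, 3L)
  expect_equal(gene_tstat(ds, "g1", rt), gene_tstat(ds_rev, "g1", rev(rt)))
  ds_swap <- ds
  ds_swap$values$s1 <- ds$values$s1[, , c(2, 1)]
  expect_equal(gene_tstat(ds_swap, "g1", rt), gene_tstat(ds, "g1", rt))
})

test_that("segmentation initialization finds the largest expression gap", {
  # clean step [0,0,4,4]: segments {1,2} and {3,4}
  ds <- series_dataset(rbind(g1 = c(0, 0, 4, 4), g2 = c(0, 0, 4, 4)))
  expect_equal(init_rt(ds, c("g1", "g2")), c(s1 = 3L))
  # monotone ramp with equal gaps: leftmost-merge tie rule gives t = 3
  ds <- series_dataset(matrix(c(0, 1, 2, 3), 1))
  expect_equal(unname(init_rt(ds, "g1")), 3L)
  # two-point grids are trivially t = 2
  ds <- series_dataset(matrix(c(0, 9), 1))
  expect_equal(unname(init_rt(ds, "g1")), 2L)
})

test_that("hill climbing reaches the planted change point", {
  mats <- list(s1 = rbind(g1 = c(0, 0, 5, 5), g2 = c(0, 0, 5, 5),
                          g3 = c(0, 0, 5, 5)))
  ds <- toy_dataset(mats)
  hc <- hill_climb_rt(ds, rownames(mats$s1), init = c(s1 = 2L))
  expect_equal(unname(hc$rt), 3L)
  # already-optimal starts do not move
  hc2 <- hill_climb_rt(ds, rownames(mats$s1), init = c(s1 = 3L))
  expect_equal(hc2$n_moves, 0L)
  expect_equal(hc2$score, hc$score)
  expect_equal(hc$score, exhaustive_rt(ds, rownames(mats$s1))$score)
})

test_that("noise-free step clusters recover their change points exactly", {
  sim <- simulate_dataset(simulation_config(
    n_samples = 3, n_timepoints = c(6, 7, 8), n_phases = 4,
    genes_per_phase = 6, n_null_genes = 0, noise_sd = 0, seed = 2))
  ds <- sim$dataset
  for (p in 1:4) {
    members <- names(sim$truth$gene_phase)[sim$truth$gene_phase == p]
    # use one sign subgroup (co-expressed); both carry the same change points
    members <- members[sim$truth$signs[members] > 0]
    hc <- hill_climb_rt(ds, members, init_rt(ds, members))
    expect_equal(unname(hc$rt), unname(sim$truth$change_index[p, ]))
  }
})

test_that("hill climbing never beats exhaustive search on small instances", {
  n_eq <- 0L
  for (i in 1:60) {
    inst <- random_step_instance(2000 + i)
    genes <- inst$dataset$genes
    hc <- hill_climb_rt(inst$dataset, genes, init_rt(inst$dataset, genes))
    ex <- exhaustive_rt(inst$dataset, genes)
    expect_gte(ex$score, hc$score - 1e-9)
    if (abs(ex$score - hc$score) <= 1e-6 * max(1, abs(ex$score)))
      n_eq <- n_eq + 1L
  }
  expect_gt(n_eq / 60, 0.9)
})
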