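test_that("quantile normalization maps worked examples correctly", {
  # two replicate columns [1,2,3] and [4,5,6] -> both become [2.5,3.5,4.5]
  ds <- toy_dataset(list(s1 = cbind(c(1, 2, 3), c(4, 5, 6))), n_rep = 1)
  qn <- quantile_normalize(ds)
  expect_equal(qn$values$s1[, 1, 1], c(2.5, 3.5, 4.5), ignore_attr = TRUE)
  expect_equal(qn$values$s1[, 2, 1], c(2.5, 3.5, 4.5), ignore_attr = TRUE)

  # ranks preserved: [3,1,2] against [6,4,5] -> first becomes [4.5,2.5,3.5]
  ds <- toy_dataset(list(s1 = cbind(c(3, 1, 2), c(6, 4, 5))), n_rep = 1)
  qn <- quantile_normalize(ds)
  expect_equal(qn$values$s1[, 1, 1], c(4.5, 2.5, 3.5), ignore_attr = TRUE)

  # identical columns are a fixed point
  ds <- toy_dataset(list(s1 = cbind(c(1, 5, 9), c(1, 5, 9))), n_rep = 1)
  expect_equal(quantile_normalize(ds), ds)
})

test_that("quantile normalization equalizes value multisets across columns", {
  set.seed(8)
  mats <- list(s1 = matrix(rnorm(40, sd = 2), 10), s2 = matrix(rexp(30), 10))
  ds <- toy_dataset(mats, n_rep = 2, jitter = 0.5)
  qn <- quantile_normalize(ds)
  cols <- list()
  for (s in sample_ids(qn)) {
    d <- qn$design[[s]]
    for (j in seq_along(d$time_points)) for (k in seq_len(d$n_replicates[j]))
      cols[[length(cols) + 1]] <- sort(unname(qn$values[[s]][, j, k]))
  }
  for (i in seq_along(cols)[-1])
    expect_equal(cols[[i]], cols[[1]], tolerance = 1e-9)
})

test_that("quantile normalization agrees with the limma reference", {
  skip_if_not_installed("limma")
  set.seed(21)
  mat <- matrix(rnorm(60), 15, 4)
  ds <- toy_dataset(list(s1 = mat), n_rep = 1)
  qn <- quantile_normalize(ds)
  ref <- limma::normalizeQuantiles(mat)
  expect_equal(qn$values$s1[, , 1], ref, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("one-gene datasets pass through quantile normalization unchanged", {
  ds <- toy_dataset(list(s1 = matrix(c(1, 2, 3), 1)), n_rep = 1)
  expect_warning(out <- quantile_normalize(ds), "one gene")
  expect_equal(out, ds)
})

test_that("linear base normalization zeroes the baseline replicate mean", {
  # T0 replicates {2,4}, value 7 at j=2 -> 4
  arr <- array(NA_real_, dim = c(1, 2, 2))
  arr[1, 1, ] <- c(2, 4); arr[1, 2, ] <- c(7, 7)
  ds <- expression_dataset("g1", list(sample_design("s1", c(0, 1), 2)),
                           list(s1 = arr))
  out <- base_normalize_linear(ds)
  expect_equal(unname(out$values$s1[1, 2, 1]), 4)
  expect_equal(mean(out$values$s1[1, 1, ]), 0)

  # single replicate series [5,8,2] -> [0,3,-3]
  ds <- series_dataset(matrix(c(5, 8, 2), 1))
  expect_equal(unname(base_normalize_linear(ds)$values$s1[1, , 1]), c(0, 3, -3))

  # constant data becomes all zero
  ds <- series_dataset(matrix(7, 3, 4), n_rep = 2)
  expect_true(all(base_normalize_linear(ds)$values$s1 == 0))
})

test_that("baseline replicate means are zero after either base normalization", {
  set.seed(3)
  ds <- toy_dataset(list(s1 = matrix(abs(rnorm(20)) * 10, 5),
                         s2 = matrix(abs(rnorm(15)) * 10, 5)),
                    n_rep = 3, jitter = 1)
  ds <- transform_values(ds, function(v, d) abs(v))
  for (out in list(base_normalize_linear(ds), base_normalize_logfold(ds))) {
    for (s in sample_ids(out)) {
      base <- out$values[[s]][, 1, , drop = FALSE]
      expect_lt(max(abs(apply(base, 1, mean, na.rm = TRUE))), 1e-12)
    }
  }
})

test_that("linear base normalization is invariant to gene-wise offsets", {
  set.seed(5)
  ds <- toy_dataset(list(s1 = matrix(rnorm(12), 3), s2 = matrix(rnorm(9), 3)),
                    n_rep = 2, jitter = 0.2)
  offset <- c(10, -4, 2.5)
  shifted <- transform_values(ds, function(v, d) v + offset)
  expect_equal(base_normalize_linear(shifted), base_normalize_linear(ds))
})

test_that("log fold change base normalization matches hand computations", {
  # log2, T0 replicates {0,0}, value 3 at j=2 -> log2(4) = 2
  arr <- array(NA_real_, dim = c(1, 2, 2))
  arr[1, 1, ] <- c(0, 0); arr[1, 2, ] <- c(3, 3)
  ds <- expression_dataset("g1", list(sample_design("s1", c(0, 1), 2)),
                           list(s1 = arr))
  expect_equal(unname(base_normalize_logfold(ds)$values$s1[1, 2, 1]), 2)

  # log2, T0 replicates {1,3}, value 7 -> 3 - (1+2)/2 = 1.5
  arr[1, 1, ] <- c(1, 3); arr[1, 2, ] <- c(7, 7)
  ds <- expression_dataset("g1", list(sample_design("s1", c(0, 1), 2)),
                           list(s1 = arr))
  expect_equal(unname(base_normalize_logfold(ds)$values$s1[1, 2, 1]), 1.5)

  # value equal to the single T0 replicate -> 0
  ds <- series_dataset(matrix(c(5, 5, 9), 1))
  expect_equal(unname(base_normalize_logfold(ds)$values$s1[1, 2, 1]), 0)

  # negative input is a domain error naming the record
  ds <- series_dataset(matrix(c(1, -2, 3), 1))
  expect_error(base_normalize_logfold(ds), "negative value.*g1")
})
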