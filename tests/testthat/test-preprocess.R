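test_that("detection filter applies the per-group presence rule at the boundary", {
  v <- matrix(1, 40, 3)
  v[, 1][c(1:10, 21:31)] <- NA    # 10/20 cases present, 9/20 controls present
  v[, 2][c(1:11, 21:31)] <- NA    # 9/20 and 9/20
  groups <- rep(c("case", "control"), each = 20)
  m <- toy_matrix(v)
  out <- detection_filter(m, groups, threshold = 0.5)
  expect_identical(colnames(out$matrix$values), c("F01", "F03"))
  expect_false(out$report$kept[out$report$feature_id == "F02"])
  expect_equal(unname(unlist(out$report[1, c("case", "control")])),
               c(0.5, 0.45))
  # fully observed matrix passes through unchanged
  full <- toy_matrix(matrix(runif(80) + 1, 20, 4))
  same <- detection_filter(full, rep(c("a", "b"), 10))
  expect_equal(same$matrix$values, full$values)
  # stricter every-group reading drops the boundary feature's neighbour
  strict <- detection_filter(m, groups, scope = "all")
  expect_identical(colnames(strict$matrix$values), "F03")
  expect_error(detection_filter(m, factor(rep("case", 40),
                                          levels = c("case", "control"))),
               "empty group")
})

test_that("sum normalization divides by the known-feature total and is scale invariant", {
  v <- matrix(c(2, 3, 5, 7), 1, 4, dimnames = list("S01", c("A", "B", "C", "D")))
  m <- feature_matrix(v, "GCTOF", known = c(TRUE, TRUE, TRUE, FALSE))
  out <- sum_normalize(m)
  expect_equal(unname(out$matrix$values[1, 1:3]), c(0.2, 0.3, 0.5))
  expect_equal(sum(out$matrix$values[1, 1:3]), 1)
  # scaling every sample by a constant leaves the output unchanged
  m2 <- feature_matrix(v * 37, "GCTOF", known = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(sum_normalize(m2)$matrix$values, out$matrix$values)
  # a single known feature becomes exactly 1
  m3 <- feature_matrix(v, "GCTOF", known = c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(sum_normalize(m3)$matrix$values[, 1]), 1)
})

test_that("pool-relative scaling and log transform behave and guard as specified", {
  v <- matrix(c(6, 4), 1, 2, dimnames = list("S01", c("A", "B")))
  m <- feature_matrix(v, "ECA", pool_reference = c(4, 4))
  out <- relative_to_pool(m)
  expect_equal(unname(out$values[1, ]), c(150, 100))
  expect_error(feature_matrix(v, "ECA", pool_reference = c(0, 4)), "positive")

  lg <- log_transform(toy_matrix(matrix(c(1, exp(1)), 1, 2)))
  expect_equal(unname(lg$values[1, ]), c(0, 1))
  bad <- toy_matrix(matrix(c(1, 2), 1, 2))
  bad$values[1, 2] <- 0
  expect_error(log_transform(bad), "non-positive value")

  # missingness preserved through the log
  vm <- matrix(c(1, NA, 2, 4), 2, 2)
  lgm <- log_transform(toy_matrix(vm))
  expect_equal(which(is.na(lgm$values)), which(is.na(vm)))
})

test_that("log of pool-relative values equals log values plus a per-feature constant", {
  syn <- generate_cohort(null_config(seed = 3))
  m <- syn$matrices$ECA
  a <- log_transform(relative_to_pool(m))$values
  b <- log_transform(m)$values
  const <- a - b
  expect_equal(const, matrix(const[1, ], nrow(const), ncol(const), byrow = TRUE,
                             dimnames = dimnames(const)))
})

test_that("half-minimum imputation completes the matrix without touching observed cells", {
  v <- matrix(c(4, NA, 8, 2, 6, 10), 3, 2)
  out <- impute_halfmin(toy_matrix(v))
  expect_equal(out$values[2, 1], 2)   # half of min(4, 8)
  expect_equal(out$values[c(1, 3), 1], v[c(1, 3), 1], ignore_attr = TRUE)
  expect_false(anyNA(out$values))
})

test_that("qq normality correlation is near 1 for normal quantiles and flags degenerate input", {
  x <- qnorm((1:50 - 0.5) / 50)
  expect_equal(qq_normality(x), 1, tolerance = 1e-12)
  expect_error(qq_normality(rep(1, 10)), "constant")
  expect_error(qq_normality(c(1, 2)), "at least 3")
  f <- tempfile(fileext = ".png")
  qq_normality(rnorm(30), plot_file = f)
  expect_true(file.exists(f))
  unlink(f)
})

test_that("heavy-tailed samples score lower qq correlation than matched normal samples", {
  # t(1) vs normal at n = 200; the heavy tail should lose in nearly every
  # seeded replicate (Monte-Carlo comparison, scaled to 200 replicates).
  set.seed(421)
  wins <- replicate(200, {
    qq_normality(rt(200, df = 1)) < qq_normality(rnorm(200))
  })
  expect_gte(mean(wins), 0.95)
})

test_that("the preprocessing chain commutes with sample reordering", {
  syn <- generate_cohort(null_config(seed = 12))
  prep <- preprocess_cohort(syn$matrices, syn$cohort)
  perm <- sample(nrow(syn$cohort))
  syn2 <- syn
  for (pf in names(syn2$matrices)) {
    syn2$matrices[[pf]]$values <- syn2$matrices[[pf]]$values[perm, ]
  }
  syn2$cohort <- syn$cohort[perm, ]
  prep2 <- preprocess_cohort(syn2$matrices, syn2$cohort)
  for (pf in names(prep$matrices)) {
    expect_equal(prep2$matrices[[pf]]$values,
                 prep$matrices[[pf]]$values[perm, , drop = FALSE])
  }
})
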