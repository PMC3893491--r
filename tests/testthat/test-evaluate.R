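test_that("midrank AUC equals brute-force pairwise concordance", {
  expect_equal(auc(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2), c(1, 1, 1, 0, 0, 0)), 8 / 9)
  expect_equal(auc(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.3, 10), rep(c(1, 0), 5)), 0.5)
  set.seed(25)
  for (i in 1:40) {
    n <- sample(6:25, 1)
    s <- sample(seq(0, 1, 0.1), n, TRUE)   # coarse grid forces ties
    y <- rbinom(n, 1, 0.5)
    if (sum(y) %in% c(0, n)) next
    expect_equal(auc(s, y), brute_auc(s, y))
    # complement identity holds exactly under midranks
    expect_equal(auc(s, y) + auc(-s, y), 1)
  }
  expect_error(auc(1:4, rep(1, 4)), "both classes")
})

test_that("ROC curve is monotone and its trapezoidal area equals the midrank AUC", {
  set.seed(26)
  s <- c(rnorm(20, 1), rnorm(25))
  y <- rep(c(1, 0), c(20, 25))
  rc <- roc_curve(s, y)
  expect_true(all(diff(rc$tpr) >= 0))
  expect_true(all(diff(rc$fpr) >= 0))
  trap <- sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
  expect_equal(trap, rc$auc, tolerance = 1e-12)
})

test_that("sensitivity and specificity follow the cutoff and Youden rules", {
  s <- c(0.9, 0.9, 0.1, 0.1)
  y <- c(1, 1, 0, 0)
  ss <- sens_spec(s, y, cutoff = 0.5)
  expect_equal(ss$sensitivity, 1)
  expect_equal(ss$specificity, 1)
  degen <- sens_spec(rep(0.6, 4), y, cutoff = 0.5)
  expect_equal(degen$sensitivity, 1)
  expect_equal(degen$specificity, 0)
  yj <- sens_spec(c(0.8, 0.6, 0.4, 0.2), y, rule = "youden")
  expect_equal(yj$sensitivity, 1)
  expect_equal(yj$specificity, 1)
})

test_that("DeLong test: identity, antisymmetry, and jackknife variance agreement", {
  set.seed(27)
  y <- rep(c(1, 0), each = 50)
  s1 <- rnorm(100) + y
  s2 <- 0.5 * s1 + rnorm(100, sd = 0.8) + 0.3 * y
  same <- delong_test(s1, s1, y)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  ab <- delong_test(s1, s2, y)
  ba <- delong_test(s2, s1, y)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p.value, ba$p.value)
  expect_error(delong_test(s1, s2[1:50], y), "equal length")

  # jackknife-over-samples oracle for each AUC variance, within 10%
  for (rep_i in 1:5) {
    sa <- rnorm(100) + 0.8 * y
    dt <- delong_test(sa, s2, y)
    jk <- jackknife_var(function(i) auc(sa[-i], y[-i]), 100)
    expect_lt(abs(dt$var_auc1 - jk) / jk, 0.10)
  }
})

test_that("two clearly different markers are separated by the DeLong test", {
  # AUCs near 0.96 vs 0.70 on a 78-sample cohort: rejection at alpha 0.05
  # in the large majority of replicates (power pattern, 40 replicates)
  set.seed(28)
  y <- rep(c(1, 0), c(40, 38))
  rej <- replicate(40, {
    strong <- rnorm(78) + 2.5 * y
    weak <- rnorm(78) + 0.74 * y
    delong_test(strong, weak, y)$p.value < 0.05
  })
  expect_gte(mean(rej), 0.75)
})

test_that("Bonferroni flags use alpha over the family size", {
  b <- bonferroni(c(0.004, 0.01, 0.2), alpha = 0.05, m = 15)
  expect_equal(b$alpha_adjusted, 0.05 / 15)
  expect_identical(b$significant, c(FALSE, FALSE, FALSE))
  expect_identical(bonferroni(c(0.001), alpha = 0.05, m = 15)$significant, TRUE)
  empty <- bonferroni(numeric(0))
  expect_length(empty$significant, 0)
  expect_identical(bonferroni(rep(1, 5))$significant, rep(FALSE, 5))
})

test_that("permutation test follows the add-one convention and flags failures", {
  y <- rep(c(1, 0), c(10, 10))
  # statistic that is maximal on the observed labeling
  stat <- function(yy) cor(yy, y)
  pt_ <- permutation_test(stat, y, B = 100, seed = 3)
  expect_equal(pt_$p.value, 1 / 101)
  expect_equal(pt_$B, 100)
  expect_length(pt_$null, 100)
  # label permutations preserve group proportions
  expect_true(all(vapply(1:5, function(i) sum(sample(y)) == 10, logical(1))))
  # failing permutations are scored at chance and counted
  flaky <- function(yy) if (any(yy != y)) stop("boom") else 1
  pf <- permutation_test(flaky, y, B = 19, seed = 4)
  expect_equal(pf$n_failed, 19)
  expect_true(all(pf$null == 0.5))
  expect_error(permutation_test(stat, y, B = 0), "at least 1")
})

test_that("distribution summary flags outliers from the median fence as specified", {
  d <- distribution_summary(c(1, 2, 3, 4, 100), rep("g", 5))
  expect_equal(d$median, 3)
  expect_equal(d$outliers[[1]], 100)
  # same flag under the conventional Tukey fence for this sample
  dt_ <- distribution_summary(c(1, 2, 3, 4, 100), rep("g", 5),
                              convention = "tukey")
  expect_equal(dt_$outliers[[1]], 100)
  none <- distribution_summary(rep(5, 8), rep("g", 8))
  expect_equal(none$n_outliers, 0)
  # symmetric data give fences symmetric about the median
  sym <- distribution_summary(c(-3, -1, 0, 1, 3), rep("g", 5))
  expect_equal(sym$fence_high - sym$median, sym$median - sym$fence_low)
  expect_error(distribution_summary(c(NA, 1), c("a", "b")), "empty group")
})
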