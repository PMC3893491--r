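test_that("vectorized rank tests agree with stats::kruskal.test column by column", {
  set.seed(10)
  X <- matrix(rnorm(60 * 8), 60, 8)
  X[, 4] <- round(X[, 4])  # induce ties
  g <- factor(sample(c("a", "b", "c"), 60, TRUE))
  out <- metabodiscrim:::kw_columns(X, g)
  for (j in 1:8) {
    kt <- kruskal.test(X[, j], g)
    expect_equal(out$statistic[j], unname(kt$statistic), tolerance = 1e-10)
    expect_equal(out$p.value[j], kt$p.value, tolerance = 1e-10)
  }
})

test_that("the stratified rank test is calibrated and matches Wilcoxon in a single stratum", {
  # one varying stratum: reduces to the (tie-corrected) two-group KW test
  set.seed(11)
  X <- matrix(rnorm(40 * 5), 40, 5)
  flag <- rep(c(TRUE, FALSE), 20)
  one <- metabodiscrim:::stratified_rank_columns(X, flag, rep("s1", 40))
  kw <- metabodiscrim:::kw_columns(X, factor(flag))
  expect_equal(one$p.value, kw$p.value, tolerance = 1e-10)
  # null calibration with two strata
  set.seed(12)
  rej <- replicate(300, {
    X <- matrix(rnorm(60), 60, 1)
    strata <- rep(c("a", "b"), c(30, 30))
    flag <- c(sample(rep(c(TRUE, FALSE), 15)), sample(rep(c(TRUE, FALSE), 15)))
    metabodiscrim:::stratified_rank_columns(X, flag, strata)$p.value < 0.05
  })
  bounds <- qbinom(c(0.005, 0.995), 300, 0.05)
  expect_gte(sum(rej), bounds[1])
  expect_lte(sum(rej), bounds[2])
})

test_that("drug-confounded features are removed with high power, signal features kept", {
  # 10 planted drug-confounded features at a standardized shift of 2.
  # Without missingness the removal rates should match the clean Wilcoxon
  # oracle (power 0.98 at the 6-vs-34 memantine split, ~1 at the 15-vs-25
  # cholinesterase split); with the default 10% MCAR missingness and
  # half-minimum imputation the rank tests are attenuated, so the
  # expectations below are frozen from oracle simulations of this world.
  hits <- integer(0); chei <- mem <- signal_kept <- logical(0)
  for (s in 1:20) {
    syn <- generate_cohort(cohort_config(seed = 300 + s, missing_rate_gctof = 0))
    prep <- preprocess_cohort(syn$matrices, syn$cohort)
    scr <- suppressWarnings(screen_confounds(prep$matrices, syn$cohort))
    dmap <- syn$truth$drug_confounded_features
    rm_ <- names(dmap) %in% scr$removed$feature_id
    chei <- c(chei, rm_[dmap == "cholinesterase_inhibitor"])
    mem <- c(mem, rm_[dmap == "memantine"])
  }
  expect_gte(mean(chei), 0.95)
  expect_gte(mean(mem), 0.90)
  for (s in 1:20) {
    syn <- generate_cohort(cohort_config(seed = 300 + s))
    prep <- preprocess_cohort(syn$matrices, syn$cohort)
    scr <- suppressWarnings(screen_confounds(prep$matrices, syn$cohort))
    hits <- c(hits, sum(names(syn$truth$drug_confounded_features) %in%
                          scr$removed$feature_id))
    signal_kept <- c(signal_kept,
                     syn$truth$signal_features %in% scr$kept$ECA)
  }
  # imputation-attenuated world: most confounds still caught
  expect_gte(mean(hits >= 8), 0.70)
  expect_gte(mean(hits) / 10, 0.80)
  # the stratified screen does not systematically discard disease signal
  expect_gte(mean(signal_kept), 0.75)
})

test_that("null cohorts lose roughly alpha x tests x features to the screen", {
  removed <- total <- 0
  for (s in 1:12) {
    syn <- generate_cohort(null_config(seed = 600 + s, n_eca = 20, n_gctof = 30,
                                       missing_rate_gctof = 0))
    prep <- preprocess_cohort(syn$matrices, syn$cohort)
    scr <- suppressWarnings(screen_confounds(prep$matrices, syn$cohort))
    removed <- removed + nrow(scr$removed)
    total <- total + 50
  }
  # three tests per feature (two AD drugs + ApoE), union removal:
  # expected rate 1 - 0.95^3 ~ 0.143
  p0 <- 1 - 0.95^3
  bounds <- qbinom(c(0.005, 0.995), total, p0)
  expect_gte(removed, bounds[1])
  expect_lte(removed, bounds[2])
})

test_that("screen structure: protein exemption, vacuous drug screen, order invariance", {
  cfg <- cohort_config(seed = 41, n_gctof = 40, n_gctof_known = 20,
                       drug_prevalence = default_drug_prevalence() * 0)
  syn <- generate_cohort(cfg)
  prep <- preprocess_cohort(syn$matrices, syn$cohort)
  # all drug flags constant -> every drug skipped with a warning, only the
  # ApoE screen runs
  warns <- capture_warnings(scr <- screen_confounds(prep$matrices, syn$cohort))
  expect_true(any(grepl("constant", warns)))
  expect_length(scr$drugs_tested, 0)
  expect_equal(scr$n_removed_drug, 0)
  expect_identical(scr$kept$PROTEIN, colnames(prep$matrices$PROTEIN$values))
  expect_true(all(scr$removed$reason == "apoe"))

  # removal decisions do not depend on feature order
  syn2 <- generate_cohort(cohort_config(seed = 42))
  prep2 <- preprocess_cohort(syn2$matrices, syn2$cohort)
  scr_a <- suppressWarnings(screen_confounds(prep2$matrices, syn2$cohort))
  perm <- sample(ncol(prep2$matrices$GCTOF$values))
  prep2$matrices$GCTOF$values <- prep2$matrices$GCTOF$values[, perm]
  prep2$matrices$GCTOF$known <- prep2$matrices$GCTOF$known[perm]
  scr_b <- suppressWarnings(screen_confounds(prep2$matrices, syn2$cohort))
  expect_setequal(scr_a$removed$feature_id, scr_b$removed$feature_id)
})
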