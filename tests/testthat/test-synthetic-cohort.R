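test_that("generation is deterministic under a seed and validates its configuration", {
  cc <- cohort_config(seed = 42)
  a <- generate_cohort(cc)
  b <- generate_cohort(cc)
  expect_identical(a, b)

  expect_error(cohort_config(n_eca = 5, n_eca_known = 10), "n_eca_known")
  expect_error(cohort_config(n_signal = 100, n_eca = 71), "n_signal")
  expect_error(cohort_config(missing_rate_gctof = 1.2), "missing_rate")
  expect_error(cohort_config(n_gctof = 5, n_gctof_known = 2,
                             n_drug_confounded = 4, n_apoe_linked = 2), "GC-TOF")
})

test_that("default cohort reproduces the emulated study margins", {
  syn <- generate_cohort(cohort_config(seed = 7))
  coh <- syn$cohort
  expect_equal(sum(coh$diagnosis == "case"), 40)
  expect_equal(sum(coh$diagnosis == "control"), 38)
  # deterministic rounding of Table-style prevalences:
  # cholinesterase inhibitors 37.5% of 40 cases = 15, controls none
  expect_equal(sum(coh$cholinesterase_inhibitor[coh$diagnosis == "case"]), 15)
  expect_equal(sum(coh$cholinesterase_inhibitor[coh$diagnosis == "control"]), 0)
  expect_equal(sum(coh$memantine[coh$diagnosis == "case"]), round(0.15 * 40))
  expect_equal(sum(coh$memantine[coh$diagnosis == "control"]), 0)
  expect_true(all(coh$mmse >= 0 & coh$mmse <= 30))
  # ApoE risk is derived from genotype
  expect_identical(coh$apoe_risk == "high",
                   coh$apoe_genotype %in% c("E3/E4", "E4/E4"))
  # MMSE lower in cases
  expect_lt(mean(coh$mmse[coh$diagnosis == "case"]),
            mean(coh$mmse[coh$diagnosis == "control"]))
  # platform shapes
  expect_equal(dim(syn$matrices$ECA$values), c(78, 71))
  expect_equal(sum(syn$matrices$ECA$known), 24)
  expect_equal(dim(syn$matrices$GCTOF$values), c(78, 299))
  expect_equal(dim(syn$matrices$PROTEIN$values), c(78, 3))
  expect_true(all(syn$matrices$ECA$pool_reference > 0))
  # missingness only on GC-TOF
  expect_false(anyNA(syn$matrices$ECA$values))
  expect_gt(mean(is.na(syn$matrices$GCTOF$values)), 0.05)
  # truth ids exist and are disjoint between signal and confound sets
  all_ids <- unlist(lapply(syn$matrices, function(m) colnames(m$values)))
  tr <- syn$truth
  expect_true(all(c(tr$signal_features, names(tr$drug_confounded_features),
                    tr$apoe_features) %in% all_ids))
  expect_length(intersect(tr$signal_features,
                          c(names(tr$drug_confounded_features), tr$apoe_features)), 0)
})

test_that("null cohorts are calibrated: feature-wise t tests reject at the nominal rate", {
  # With all effects zero, case and control feature values are identical in
  # law. Aggregate the rejection indicator over many independent null
  # features and check against a 99% binomial interval around 0.05.
  reject <- integer(0)
  for (s in 1:5) {
    syn <- generate_cohort(null_config(seed = s, n_eca = 30, n_gctof = 40,
                                       missing_rate_gctof = 0))
    case <- syn$cohort$diagnosis == "case"
    for (m in syn$matrices[c("ECA", "GCTOF")]) {
      lv <- log(m$values)
      reject <- c(reject, apply(lv, 2, function(v)
        two_sample_t(v[case], v[!case])$p.value < 0.05))
    }
  }
  n <- length(reject)
  bounds <- qbinom(c(0.005, 0.995), n, 0.05)
  expect_gte(sum(reject), bounds[1])
  expect_lte(sum(reject), bounds[2])
})

test_that("planted standardized effects are recovered empirically at large n", {
  cc <- cohort_config(n_cases = 500, n_controls = 500, seed = 99,
                      signal_effect = 2)
  syn <- generate_cohort(cc)
  case <- syn$cohort$diagnosis == "case"
  lv <- log(syn$matrices$ECA$values)
  for (f in syn$truth$signal_features) {
    d <- (mean(lv[case, f]) - mean(lv[!case, f])) /
      sd(lv[!case, f])
    se <- sqrt(1 / sum(case) + 1 / sum(!case) + d^2 / (2 * (sum(case) + sum(!case))))
    expect_lt(abs(d - 2), 3 * se)
  }
})

test_that("cohort round-trips losslessly through the TSV/JSON serialization", {
  syn <- generate_cohort(cohort_config(n_eca = 8, n_eca_known = 4,
                                       n_gctof = 12, n_gctof_known = 6,
                                       n_drug_confounded = 2, n_apoe_linked = 1,
                                       seed = 5))
  dir <- tempfile("cohort")
  write_cohort(syn, dir)
  back <- read_cohort(dir)
  expect_equal(back$cohort, syn$cohort)
  for (pf in names(syn$matrices)) {
    expect_equal(back$matrices[[pf]]$values, syn$matrices[[pf]]$values)
    expect_equal(back$matrices[[pf]]$known, syn$matrices[[pf]]$known)
    expect_equal(back$matrices[[pf]]$pool_reference,
                 syn$matrices[[pf]]$pool_reference)
  }
  expect_equal(back$truth$signal_features, syn$truth$signal_features)
  expect_equal(back$truth$drug_confounded_features,
               syn$truth$drug_confounded_features)
  # missing cells come back as NA, not zero
  expect_equal(which(is.na(back$matrices$GCTOF$values)),
               which(is.na(syn$matrices$GCTOF$values)))
  unlink(dir, recursive = TRUE)
})

test_that("malformed tables are rejected with informative errors", {
  syn <- generate_cohort(null_config(seed = 1, n_eca = 4, n_gctof = 4))
  dir <- tempfile("bad")
  write_cohort(syn, dir)
  # duplicate a sample id in a feature table
  f <- file.path(dir, "features_ECA.tsv")
  lines <- readLines(f)
  lines[3] <- sub("^S[0-9]+", "S001", lines[3])
  writeLines(lines, f)
  expect_error(read_cohort(dir), "S001")
  # non-numeric cell
  write_cohort(syn, dir)
  lines <- readLines(f)
  lines[3] <- sub("^(S[0-9]+\t)[0-9.]+", "\\1oops", lines[3])
  writeLines(lines, f)
  expect_error(read_cohort(dir), "non-numeric")
  unlink(dir, recursive = TRUE)
})
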