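DRUG_CLASSES <- c("antidepressant", "antipsychotic", "anxiolytic",
                  "corticosteroid", "cholinesterase_inhibitor", "memantine",
                  "statin")

APOE_HIGH_RISK <- c("E3/E4", "E4/E4")

default_drug_prevalence <- function() {
  # Case/control prevalences of the seven recorded drug classes in the
  # emulated cohort: the two AD treatment drugs are case-exclusive.
  matrix(c(0.300, 0.2105,
           0.050, 0.0,
           0.125, 0.132,
           0.025, 0.132,
           0.375, 0.0,
           0.150, 0.0,
           0.200, 0.263),
         nrow = 7, byrow = TRUE,
         dimnames = list(DRUG_CLASSES, c("case", "control")))
}

#' Configuration of the synthetic CSF cohort generator
#'
#' Describes a two-group CSF biomarker study: a liquid-chromatography
#' electrochemical-array (ECA) metabolite panel quantified relative to a
#' pooled reference, a GC-TOF mass-spectrometry metabolite panel with
#' missing peaks, and a three-analyte protein panel (amyloid-beta 1-42,
#' total tau, phospho-tau). Disease-discriminative features are planted on
#' the ECA platform; drug-confounded and ApoE-linked features on the GC-TOF
#' platform. All effects are standardized shifts on the log scale, in units
#' of the log-intensity standard deviation.
#'
#' @param n_cases,n_controls Group sizes (defaults 40 and 38).
#' @param n_eca,n_eca_known ECA feature counts (defaults 71 total, 24 known).
#' @param n_gctof,n_gctof_known GC-TOF feature counts (defaults 299 total,
#'   160 matched to the spectral library of identified compounds).
#' @param n_protein Number of protein analytes (default 3).
#' @param n_signal Number of planted disease-discriminative ECA features.
#' @param signal_effect Standardized log-scale mean shift of signal features
#'   in cases.
#' @param n_drug_confounded Number of GC-TOF features shifted in users of an
#'   AD treatment drug (assigned alternately to cholinesterase inhibitors
#'   and memantine).
#' @param drug_effect Standardized shift in users of the assigned drug.
#' @param n_apoe_linked Number of GC-TOF features shifted in high-risk ApoE
#'   carriers (E3/E4 or E4/E4).
#' @param apoe_effect Standardized shift in high-risk carriers.
#' @param drug_prevalence 7 x 2 matrix of per-drug case/control use rates;
#'   see `default_drug_prevalence` values in the source for the defaults.
#' @param apoe_high_risk_rate Length-2 vector: probability of a high-risk
#'   genotype in cases and controls.
#' @param missing_rate_gctof Fraction of GC-TOF entries missing completely
#'   at random.
#' @param protein_effects Named signed standardized shifts of the protein
#'   analytes in cases (amyloid-beta down, tau species up).
#' @param sdlog Log-scale standard deviation of feature intensities.
#' @param rho Optional equicorrelation of log intensities within a platform.
#' @param seed Integer seed; identical configurations generate identical
#'   cohorts.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 40, n_controls = 38,
                          n_eca = 71, n_eca_known = 24,
                          n_gctof = 299, n_gctof_known = 160,
                          n_protein = 3,
                          n_signal = 2, signal_effect = 2,
                          n_drug_confounded = 10, drug_effect = 2,
                          n_apoe_linked = 2, apoe_effect = 2,
                          drug_prevalence = default_drug_prevalence(),
                          apoe_high_risk_rate = c(case = 0.5, control = 0.25),
                          missing_rate_gctof = 0.10,
                          protein_effects = c(abeta42 = -1.5, ttau = 1.2, ptau = 1.2),
                          sdlog = 0.5, rho = 0, seed = NULL) {
  cfg <- list(n_cases = n_cases, n_controls = n_controls,
              n_eca = n_eca, n_eca_known = n_eca_known,
              n_gctof = n_gctof, n_gctof_known = n_gctof_known,
              n_protein = n_protein,
              n_signal = n_signal, signal_effect = signal_effect,
              n_drug_confounded = n_drug_confounded, drug_effect = drug_effect,
              n_apoe_linked = n_apoe_linked, apoe_effect = apoe_effect,
              drug_prevalence = drug_prevalence,
              apoe_high_risk_rate = apoe_high_risk_rate,
              missing_rate_gctof = missing_rate_gctof,
              protein_effects = protein_effects,
              sdlog = sdlog, rho = rho, seed = seed)
  counts <- c("n_cases", "n_controls", "n_eca", "n_eca_known", "n_gctof",
              "n_gctof_known", "n_protein", "n_signal", "n_drug_confounded",
              "n_apoe_linked")
  for (nm in counts) {
    v <- cfg[[nm]]
    if (length(v) != 1 || !is.finite(v) || v < 0 || v != round(v)) {
      stopf("configuration error: '%s' must be a non-negative integer", nm)
    }
  }
  if (cfg$n_eca_known > cfg$n_eca) {
    stopf("configuration error: n_eca_known exceeds n_eca")
  }
  if (cfg$n_gctof_known > cfg$n_gctof) {
    stopf("configuration error: n_gctof_known exceeds n_gctof")
  }
  if (cfg$n_signal > cfg$n_eca) {
    stopf("configuration error: n_signal exceeds the ECA feature count")
  }
  if (cfg$n_drug_confounded + cfg$n_apoe_linked > cfg$n_gctof) {
    stopf("configuration error: drug-confounded plus ApoE-linked features exceed the GC-TOF feature count")
  }
  if (cfg$n_signal + cfg$n_drug_confounded + cfg$n_apoe_linked >
      cfg$n_eca + cfg$n_gctof) {
    stopf("configuration error: planted features exceed the total feature count")
  }
  if (!is.matrix(drug_prevalence) || nrow(drug_prevalence) != length(DRUG_CLASSES) ||
      ncol(drug_prevalence) != 2) {
    stopf("configuration error: drug_prevalence must be a 7 x 2 matrix")
  }
  if (any(drug_prevalence < 0 | drug_prevalence > 1)) {
    stopf("configuration error: drug prevalences must lie in [0, 1]")
  }
  if (any(apoe_high_risk_rate < 0 | apoe_high_risk_rate > 1)) {
    stopf("configuration error: apoe_high_risk_rate must lie in [0, 1]")
  }
  if (missing_rate_gctof < 0 || missing_rate_gctof >= 1) {
    stopf("configuration error: missing_rate_gctof must lie in [0, 1)")
  }
  if (length(protein_effects) != cfg$n_protein) {
    stopf("configuration error: protein_effects must have one entry per protein analyte")
  }
  if (cfg$rho < 0 || cfg$rho >= 1) {
    stopf("configuration error: rho must lie in [0, 1)")
  }
  if (cfg$sdlog <= 0) stopf("configuration error: sdlog must be positive")
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d cases / %d controls; ECA %d (%d known), GC-TOF %d (%d known), %d proteins\n",
              x$n_cases, x$n_controls, x$n_eca, x$n_eca_known, x$n_gctof,
              x$n_gctof_known, x$n_protein))
  cat(sprintf("  planted: %d signal (d=%.2g), %d drug-confounded (d=%.2g), %d ApoE-linked (d=%.2g)\n",
              x$n_signal, x$signal_effect, x$n_drug_confounded, x$drug_effect,
              x$n_apoe_linked, x$apoe_effect))
  invisible(x)
}

# deterministic rounding of prevalence x group size, random assignment of carriers
assign_flags <- function(n, prevalence) {
  k <- round(prevalence * n)
  flag <- rep(FALSE, n)
  if (k > 0) flag[sample.int(n, k)] <- TRUE
  flag
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

# equicorrelated standard normal draws: n x p
req_norm <- function(n, p, rho) {
  z <- matrix(stats::rnorm(n * p), n, p)
  if (rho > 0) {
    g <- stats::rnorm(n)
    z <- sqrt(rho) * g + sqrt(1 - rho) * z
  }
  z
}

#' Generate a synthetic two-platform CSF cohort
#'
#' Draws per-sample metadata (diagnosis, demographics, MMSE, seven drug-class
#' flags, ApoE genotype) and log-normal feature tables for the ECA, GC-TOF
#' and protein platforms, planting disease-discriminative, drug-confounded
#' and ApoE-linked effects as specified by the configuration, and returns the
#' ground truth of what was planted so downstream recovery can be scored.
#'
#' Drug flags are assigned by deterministic rounding of prevalence times
#' group size (so the cohort margins reproduce the configured rates exactly)
#' followed by random assignment of which samples carry each flag. GC-TOF
#' entries are set missing completely at random at the configured rate.
#'
#' @param config A [cohort_config()] object.
#' @return A list of class `synthetic_cohort` with elements `cohort`
#'   (data.frame of per-sample metadata), `matrices` (named list of
#'   [feature_matrix()] objects: `ECA`, `GCTOF`, `PROTEIN`), and `truth`
#'   (planted feature ids and true standardized effects).
#' @examples
#' cc <- cohort_config(seed = 1)
#' syn <- generate_cohort(cc)
#' table(syn$cohort$diagnosis)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stopf("'config' must be created by cohort_config()")
  }
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n1 <- cfg$n_cases; n0 <- cfg$n_controls; n <- n1 + n0
  ids <- sprintf("S%03d", seq_len(n))
  diagnosis <- factor(rep(c("case", "control"), c(n1, n0)),
                      levels = c("control", "case"))
  is_case <- diagnosis == "case"

  age <- round(c(stats::rnorm(n1, 69.0, 9.1), stats::rnorm(n0, 69.5, 9.7)), 1)
  education <- round(rtrunc_norm(n, ifelse(is_case, 14.8, 16.6),
                                 ifelse(is_case, 3.6, 3.0), 6, 22))
  mmse <- round(rtrunc_norm(n, ifelse(is_case, 19.9, 29.2),
                            ifelse(is_case, 7.7, 1.3), 0, 30))
  sex <- factor(ifelse(stats::runif(n) < ifelse(is_case, 0.25, 0.342),
                       "male", "female"), levels = c("female", "male"))
  race <- factor(ifelse(stats::runif(n) < ifelse(is_case, 0.825, 0.868),
                        "caucasian", "other"), levels = c("caucasian", "other"))

  drugs <- matrix(FALSE, n, length(DRUG_CLASSES),
                  dimnames = list(ids, DRUG_CLASSES))
  for (d in DRUG_CLASSES) {
    drugs[is_case, d] <- assign_flags(n1, cfg$drug_prevalence[d, "case"])
    drugs[!is_case, d] <- assign_flags(n0, cfg$drug_prevalence[d, "control"])
  }

  high <- stats::runif(n) < ifelse(is_case, cfg$apoe_high_risk_rate[["case"]],
                                   cfg$apoe_high_risk_rate[["control"]])
  geno <- character(n)
  geno[high] <- sample(c("E3/E4", "E4/E4"), sum(high), TRUE, prob = c(0.8, 0.2))
  geno[!high] <- sample(c("E3/E3", "E2/E3", "E2/E4", "E2/E2"), sum(!high), TRUE,
                        prob = c(0.70, 0.15, 0.10, 0.05))
  apoe_risk <- factor(ifelse(geno %in% APOE_HIGH_RISK, "high", "low"),
                      levels = c("low", "high"))

  cohort <- data.frame(sample_id = ids, diagnosis = diagnosis, age = age,
                       sex = sex, race = race, education = education,
                       mmse = mmse, as.data.frame(drugs),
                       apoe_genotype = geno, apoe_risk = apoe_risk,
                       stringsAsFactors = FALSE, row.names = NULL)

  # --- planted feature assignment -------------------------------------
  eca_ids <- c(sprintf("ECA_K%02d", seq_len(cfg$n_eca_known)),
               sprintf("ECA_U%02d", seq_len(cfg$n_eca - cfg$n_eca_known)))
  gctof_ids <- c(sprintf("GCTOF_K%03d", seq_len(cfg$n_gctof_known)),
                 sprintf("GCTOF_U%03d", seq_len(cfg$n_gctof - cfg$n_gctof_known)))
  prot_ids <- names(cfg$protein_effects) %||% sprintf("PROT_%d", seq_len(cfg$n_protein))

  # signal features: the unknown ECA channels first, mirroring the emulated
  # study where the strongest discriminators were unidentified ECA features
  eca_unknown_first <- c(eca_ids[-seq_len(cfg$n_eca_known)],
                         eca_ids[seq_len(min(cfg$n_eca_known, cfg$n_eca))])
  signal_features <- utils::head(eca_unknown_first, cfg$n_signal)

  gctof_pick <- sample(gctof_ids, cfg$n_drug_confounded + cfg$n_apoe_linked)
  drug_features <- utils::head(gctof_pick, cfg$n_drug_confounded)
  apoe_features <- utils::tail(gctof_pick, cfg$n_apoe_linked)
  ad_drugs <- c("cholinesterase_inhibitor", "memantine")
  drug_map <- if (cfg$n_drug_confounded > 0) {
    stats::setNames(rep(ad_drugs, length.out = cfg$n_drug_confounded), drug_features)
  } else stats::setNames(character(0), character(0))

  # --- feature tables --------------------------------------------------
  make_platform <- function(feat_ids, mu, known, platform, shifts) {
    p <- length(feat_ids)
    if (p == 0) return(NULL)
    z <- req_norm(n, p, cfg$rho)
    logx <- matrix(mu, n, p, byrow = TRUE) + cfg$sdlog * (shifts + z)
    vals <- exp(logx)
    dimnames(vals) <- list(ids, feat_ids)
    pool <- NULL
    if (platform == "ECA") {
      # pool reference: the pooled CSF sample measured once per feature
      pool <- exp(mu + cfg$sdlog * 0.1 * stats::rnorm(p))
    }
    feature_matrix(vals, platform, known, pool)
  }

  shift_mat <- function(feat_ids) matrix(0, n, length(feat_ids),
                                         dimnames = list(NULL, feat_ids))

  s_eca <- shift_mat(eca_ids)
  for (f in signal_features) s_eca[is_case, f] <- cfg$signal_effect
  mu_eca <- rep(log(100), cfg$n_eca)  # pool-relative scale, pool near 100%
  mat_eca <- make_platform(eca_ids, mu_eca,
                           seq_len(cfg$n_eca) <= cfg$n_eca_known, "ECA", s_eca)

  s_gc <- shift_mat(gctof_ids)
  for (f in drug_features) s_gc[drugs[, drug_map[[f]]], f] <- cfg$drug_effect
  for (f in apoe_features) s_gc[apoe_risk == "high", f] <- cfg$apoe_effect
  mu_gc <- stats::runif(cfg$n_gctof, log(1e4), log(1e6))
  mat_gc <- make_platform(gctof_ids, mu_gc,
                          seq_len(cfg$n_gctof) <= cfg$n_gctof_known, "GCTOF", s_gc)
  if (!is.null(mat_gc) && cfg$missing_rate_gctof > 0) {
    mask <- matrix(stats::runif(n * cfg$n_gctof) < cfg$missing_rate_gctof,
                   n, cfg$n_gctof)
    mat_gc$values[mask] <- NA_real_
  }

  s_pr <- shift_mat(prot_ids)
  for (j in seq_along(prot_ids)) s_pr[is_case, j] <- cfg$protein_effects[[j]]
  mu_pr <- log(c(250, 60, 25))[seq_len(cfg$n_protein)]  # pg/ml-scale levels
  mu_pr[is.na(mu_pr)] <- log(50)
  mat_pr <- make_platform(prot_ids, mu_pr, rep(TRUE, cfg$n_protein),
                          "PROTEIN", s_pr)

  matrices <- Filter(Negate(is.null),
                     list(ECA = mat_eca, GCTOF = mat_gc, PROTEIN = mat_pr))

  effects <- c(stats::setNames(rep(cfg$signal_effect, length(signal_features)),
                               signal_features),
               stats::setNames(rep(cfg$drug_effect, length(drug_features)),
                               drug_features),
               stats::setNames(rep(cfg$apoe_effect, length(apoe_features)),
                               apoe_features))
  truth <- list(signal_features = signal_features,
                drug_confounded_features = drug_map,
                apoe_features = apoe_features,
                effects = effects)

  structure(list(cohort = cohort, matrices = matrices, truth = truth,
                 config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d cases / %d controls; platforms: %s\n",
              sum(x$cohort$diagnosis == "case"),
              sum(x$cohort$diagnosis == "control"),
              paste(names(x$matrices), collapse = ", ")))
  invisible(x)
}
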