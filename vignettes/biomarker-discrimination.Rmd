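---
title: "Cross-validated stepwise discrimination for CSF metabolomic biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-validated stepwise discrimination for CSF metabolomic biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabodiscrim)
```

## The problem

Cerebrospinal-fluid (CSF) metabolomic panels are candidate diagnostic
markers for Alzheimer's disease (AD). A typical discovery study measures a
few hundred relative metabolite concentrations on two platforms — a
liquid-chromatography electrochemical array (ECA, quantified against a
pooled CSF reference) and GC-TOF mass spectrometry (normalized to the summed
intensity of identified compounds) — alongside the established protein
markers amyloid-beta 1-42, total tau and phospho-tau, in a small
case-control cohort (here 40 cases, 38 controls). Two difficulties dominate
the statistics:

1. **Confounding by treatment and genotype.** AD drugs (cholinesterase
   inhibitors, memantine) are taken almost exclusively by cases, so any
   metabolite perturbed by treatment masquerades as a disease marker.
   Likewise the ApoE risk genotype (E3/E4, E4/E4) is enriched in cases.
2. **Overfitting at n = 78 with p in the hundreds.** Apparent (training)
   discrimination is meaningless; selection stability and held-out
   performance are the quantities of interest.

`metabodiscrim` implements the corresponding analysis pipeline as a tested,
reusable package, together with a synthetic cohort generator so that every
stage — including its error rates — can be exercised without access to any
clinical data.

## The model-building engine

The core estimator, `stepcv()`, is forward stepwise logistic regression
under the Bayesian Information Criterion, nested in stratified five-fold
cross-validation:

* Each 4/5 training split grows a logistic model from the intercept,
  adding at every step the candidate feature whose refit attains the lowest
  BIC (`-2 log L + k log n`, `k` counting the intercept), stopping when no
  addition lowers BIC. Ties break deterministically by feature id.
  Candidate fits exhibiting quasi-complete separation are skipped.
* Per fold, the selected variables, training AUC and held-out testing AUC
  are recorded. A model's headline discrimination is the **mean testing
  AUC** across folds — never the refit's apparent AUC.
* The final variable set is chosen by **cross-validation consistency**:
  features selected in at least 3 of 5 folds; if none reach the threshold,
  the features with the maximal selection count (the literal
  "selected in the most cross-validation models" rule). The final
  coefficients are a refit on all samples, ridge-stabilized (1e-6) only if
  that refit separates, and only for reporting.

Sensitivity and specificity are computed from the pooled out-of-fold
predicted probabilities at the 0.5 cutoff (a Youden-maximizing rule is
available in `sens_spec()`), and the paired DeLong test also operates on
pooled out-of-fold predictions, so model comparisons never touch training
predictions.

Significance of a whole model is assessed by a **whole-pipeline permutation
test**: case labels are shuffled preserving group sizes, the *entire*
procedure — confound screen included — is re-run per permutation, and the
empirical p-value uses the add-one convention
`(1 + #{null >= observed}) / (B + 1)`, so p is never zero. The permuted
statistic is the mean testing AUC; `permutation_test()` accepts any scalar
statistic closure, since the original description of the permuted statistic
("best correlation coefficient and AUC") is ambiguous.

## Confound screening and its scope

`screen_confounds()` follows the published sequence: drug classes nominally
associated with diagnosis (two-sided Fisher, p < 0.05) are identified
first; then every metabolite is rank-tested against each such drug flag and
against the binary ApoE risk grouping; metabolites with any confound
p < 0.05 are removed before model building. Protein analytes are exempt.
No multiple-testing correction is applied at this stage — the filter is
deliberately conservative in the direction of removing too much.

One design question the original description leaves open is *which samples
enter the rank tests*. Pooling all samples is the literal reading, but
when a drug is taken only by cases, a pooled metabolite-vs-drug test is
confounded with diagnosis itself: in synthetic cohorts it removes genuine
disease markers almost every time (planted signal features survive pooled
screening in ~3% of replicates, versus ~86% under stratification). The
package therefore defaults to a **diagnosis-stratified two-group rank
test** (a van Elteren-type combination of within-stratum, tie-corrected
Wilcoxon statistics referred to chi-square with 1 df), which tests the
drug/genotype association at fixed disease status. `scope = "pooled"`
restores the literal pooled Kruskal-Wallis behavior for comparison.

Screening happens once, before cross-validation, mirroring the original
sequence. The leakage this implies (the screen sees all labels) is the
reason the permutation test re-runs the screen inside each permutation;
`permute_rescreen = FALSE` disables that for sensitivity analysis.

## The synthetic cohort generator

`generate_cohort()` draws the world the analysis assumes:

* **Cohort**: 40 cases / 38 controls; age ~69 in both groups; education
  slightly higher in controls; MMSE 19.9 +/- 7.7 in cases vs 29.2 +/- 1.3 in
  controls (truncated to 0-30); seven drug-class flags assigned by
  deterministic rounding of the group prevalence times group size (so the
  cohort margins reproduce the configured rates exactly) with random
  carrier assignment; ApoE genotypes with high-risk (E3/E4, E4/E4)
  probability 0.50 in cases and 0.25 in controls, typical of AD cohorts.
* **Features**: log-normal intensities (log-scale SD 0.5, chosen as a
  realistic relative-intensity CV; all planted effects are *standardized*
  shifts so this choice does not affect discriminability). ECA features are
  generated around a pool reference near 100%; GC-TOF intensities span
  1e4-1e6 with 10% of entries missing completely at random (the true
  below-detection mechanism is not modeled); protein analytes sit at
  CSF-typical pg/ml levels with amyloid-beta shifted down and the tau
  species up in cases.
* **Planted structure**: 2 disease-discriminative ECA features
  (standardized shift 2 — two independent features at shift 2 imply a
  theoretical combined AUC of Phi(2) ~ 0.98, matching the strongest
  published panel's range), 10 drug-confounded GC-TOF features (shift 2 in
  users, assigned alternately to the two AD drugs), and 2 ApoE-linked
  GC-TOF features (shift 2 in high-risk carriers). Feature correlation
  defaults to independence with an optional equicorrelation `rho`, since no
  covariance information is available to emulate.

What a green test on this world does *not* establish: robustness to
correlated metabolite blocks, informative (below-detection) missingness,
batch effects, or platform drift — none of which the generator emulates.

## Numerical choices

* Logistic fits use IRLS with step-halving to a gradient tolerance of 1e-8
  (max 100 iterations). Quasi-complete separation is flagged when a
  standardized slope exceeds 12 (a fitted log-odds-ratio of e^12 per SD is
  indistinguishable from divergence at n = 78).
* The stepwise scan fits every single-feature addition exactly when the
  extended model has 2 or 3 parameters (vectorized IRLS with closed-form
  Newton solves). For deeper models, candidates are first ranked by the
  Rao score statistic of the addition — computable for all candidates from
  one matrix product, the device `stats::add1.glm` uses — and the top 15
  are refit exactly; the score statistic agrees with the likelihood ratio
  to first order, and on 6-feature pools (where everything is refit
  exactly) forward selection matches exhaustive subset search in >= 95% of
  replicates.
* The Kruskal-Wallis and stratified rank statistics use midranks with the
  standard tie correction; an all-tied column scores H = 0, p = 1 by
  convention.
* Missing GC-TOF values surviving the detection filter are imputed with
  half the feature's minimum observed value before the log transform
  (logistic regression needs complete rows; the original handling is
  unstated). This is configurable (`impute = "none"`), and it measurably
  attenuates the drug screen for small user groups — with 10% missingness
  the memantine-confounded features (6 users) are caught ~79% of the time
  versus ~96% without missingness.
* Natural log throughout (the base only shifts coefficients); the
  detection filter keeps a feature present in at least 50% of *at least
  one* diagnosis group, so case-only metabolites survive
  (`scope = "all"` gives the stricter reading).
* Box-plot outliers are flagged beyond 1.5 IQR from the *median* — the
  original figure's stated, nonstandard convention — with the usual Tukey
  quartile fences available (`convention = "tukey"`).

## A worked run

```{r run, eval = FALSE}
cfg <- run_config(pools = c("E", "M", "P", "P|E", "P|M", "P|M|E"),
                  B = 199, seed = 1)
report <- run_all(cfg)
report
render_report(report, "results/")
```

`run_all()` echoes every derived seed in its output, and a rerun with an
identical configuration produces a byte-identical JSON bundle. `B`
defaults to 199 for desk-scale runs; set `B = 1000` for the full
permutation analysis.

## Known limitations

* Screening before cross-validation (the emulated design) optimistically
  biases the cross-validated AUC when confounds correlate with diagnosis;
  the permutation test, which repeats the screen under permuted labels, is
  the package's honest significance statement.
* The consistency-selected "final model" is a descriptive summary; its
  all-sample refit coefficients inherit selection bias and should not be
  read as unbiased effect estimates.
* At n = 78, quasi-complete separation of strong marker combinations is
  common; flagged fits are skipped during selection, which slightly
  shortens stepwise paths for very strong signals.
* The alpha-level confound screen removes each true disease marker with
  probability roughly `1 - (1 - alpha)^(number of confound tests)` (about
  14% at defaults) — the price of the conservative filtering strategy, and
  the dominant failure mode in recovery simulations.
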