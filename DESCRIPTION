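Package: metabodiscrim
Title: Cross-Validated Stepwise Logistic Discrimination for CSF Metabolomic Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case-control biomarker discovery from cerebrospinal-fluid
    metabolomic and protein panels. Implements platform-specific preprocessing
    (pool-relative scaling, sum normalization over known metabolites, detection
    filtering, log transformation), univariate demographic tests and
    drug/ApoE confound screening, forward stepwise logistic regression under
    the Bayesian Information Criterion nested in stratified five-fold
    cross-validation with consistency-based variable selection, whole-pipeline
    permutation significance, paired DeLong AUC comparisons with Bonferroni
    correction, and a seeded synthetic cohort generator emulating a two-platform
    Alzheimer's disease CSF study for power and calibration analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
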