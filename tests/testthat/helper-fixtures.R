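# Shared fixtures: small cohort configurations and independent oracles.

# A null cohort: no planted effects anywhere, modest feature counts.
null_config <- function(seed, n_eca = 6, n_gctof = 10, ...) {
  cohort_config(n_eca = n_eca, n_eca_known = max(1, n_eca %/% 2),
                n_gctof = n_gctof, n_gctof_known = max(1, n_gctof %/% 2),
                n_signal = 0, n_drug_confounded = 0, n_apoe_linked = 0,
                signal_effect = 0, drug_effect = 0, apoe_effect = 0,
                protein_effects = c(abeta42 = 0, ttau = 0, ptau = 0),
                seed = seed, ...)
}

# A tiny hand-made feature_matrix for unit tests.
toy_matrix <- function(values, platform = "GCTOF", known = NULL, pool = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("S%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("F%02d", seq_len(ncol(values)))
  }
  feature_matrix(values, platform,
                 known %||% rep(TRUE, ncol(values)), pool)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles -----------------------------------------------

# Two-sided Fisher p by full enumeration of the hypergeometric support:
# sum the probabilities of all tables with the observed margins whose
# probability does not exceed the observed table's (with a relative
# tolerance for float comparison, as in the classical definition).
enum_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Brute-force pairwise concordance AUC.
brute_auc <- function(scores, labels) {
  cs <- scores[labels == 1]; ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# Exhaustive min-BIC subset search with stats::glm as the independent
# fitter (small pools only).
exhaustive_bic <- function(x, y) {
  p <- ncol(x)
  best <- list(bic = Inf, subset = integer(0))
  for (mask in 0:(2^p - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    fit <- if (length(idx)) {
      suppressWarnings(stats::glm(y ~ x[, idx, drop = FALSE], family = stats::binomial))
    } else suppressWarnings(stats::glm(y ~ 1, family = stats::binomial))
    bic <- -2 * as.numeric(stats::logLik(fit)) + (length(idx) + 1) * log(length(y))
    if (bic < best$bic) best <- list(bic = bic, subset = idx)
  }
  best
}

# Leave-one-out jackknife variance of a statistic over samples.
jackknife_var <- function(stat, n) {
  th <- vapply(seq_len(n), stat, numeric(1))
  (n - 1) / n * sum((th - mean(th))^2)
}
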