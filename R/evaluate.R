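#' Area under the ROC curve
#'
#' Midrank (tie-corrected) Mann-Whitney AUC: the probability that a random
#' case scores above a random control, counting ties as one half. Equals
#' the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric classifier scores (higher = more case-like).
#' @param labels Binary labels (case = 1/TRUE/second factor level).
#' @return AUC in \\[0, 1\\].
#' @export
auc <- function(scores, labels) {
  y <- coerce_binary(labels)
  n1 <- sum(y); n0 <- length(y) - n1
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' @inheritParams auc
#' @return List of class `roc` with `thresholds`, `tpr`, `fpr`, `auc`,
#'   `n_cases`, `n_controls`.
#' @export
roc_curve <- function(scores, labels) {
  y <- coerce_binary(labels)
  n1 <- sum(y); n0 <- length(y) - n1
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / n0, numeric(1))
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr,
                 auc = auc(scores, y), n_cases = n1, n_controls = n0),
            class = "roc")
}

#' Sensitivity and specificity at a probability cutoff
#'
#' Scores at or above the cutoff are called positive. `rule = "youden"`
#' instead picks the observed threshold maximizing sensitivity +
#' specificity - 1.
#'
#' @inheritParams auc
#' @param cutoff Probability cutoff (default 0.5).
#' @param rule `"cutoff"` (default) or `"youden"`.
#' @return List with `sensitivity`, `specificity`, and the `threshold` used.
#' @export
sens_spec <- function(scores, labels, cutoff = 0.5,
                      rule = c("cutoff", "youden")) {
  rule <- match.arg(rule)
  y <- coerce_binary(labels)
  if (sum(y) == 0 || sum(y) == length(y)) stopf("both classes must be present")
  if (rule == "youden") {
    rc <- roc_curve(scores, y)
    j <- which.max(rc$tpr - rc$fpr)
    cutoff <- rc$thresholds[j]
  }
  pos <- scores >= cutoff
  list(sensitivity = sum(pos & y == 1) / sum(y == 1),
       specificity = sum(!pos & y == 0) / sum(y == 0),
       threshold = cutoff)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Nonparametric comparison of the AUCs of two classifiers scored on the
#' same samples, via per-sample placement values (structural components):
#' the variance of each AUC and their covariance are estimated from the
#' empirical variance of case placements (scaled by 1/n_cases) and control
#' placements (scaled by 1/n_controls), and the AUC difference is referred
#' to a standard normal.
#'
#' @param scores1,scores2 Score vectors of the two models on the same
#'   samples.
#' @param labels Binary labels.
#' @return Object of class `delong_test` with `auc1`, `auc2`, `var_diff`,
#'   `var_auc1`, `var_auc2`, `statistic` (z), `p.value`.
#' @export
delong_test <- function(scores1, scores2, labels) {
  y <- coerce_binary(labels)
  if (length(scores1) != length(scores2) || length(scores1) != length(y)) {
    stopf("score vectors and labels must have equal length")
  }
  n1 <- sum(y); n0 <- length(y) - n1
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  placements <- function(s) {
    cs <- s[y == 1]; ct <- s[y == 0]
    psi <- outer(cs, ct, function(a, b) (a > b) + 0.5 * (a == b))
    list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
  }
  p1 <- placements(scores1)
  p2 <- placements(scores2)
  s10 <- stats::cov(cbind(p1$v10, p2$v10))
  s01 <- stats::cov(cbind(p1$v01, p2$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  var_auc1 <- s10[1, 1] / n1 + s01[1, 1] / n0
  var_auc2 <- s10[2, 2] / n1 + s01[2, 2] / n0
  d <- p1$auc - p2$auc
  if (var_diff <= 0) {
    z <- 0
    p <- if (abs(d) < 1e-12) 1 else NA_real_
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc1 = p1$auc, auc2 = p2$auc, var_diff = var_diff,
                 var_auc1 = var_auc1, var_auc2 = var_auc2,
                 statistic = z, p.value = p),
            class = "delong_test")
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf("DeLong paired AUC test: AUC1 = %.3f, AUC2 = %.3f, z = %.3f, p = %.4g\n",
              x$auc1, x$auc2, x$statistic, x$p.value))
  invisible(x)
}

#' Bonferroni correction flags
#'
#' @param pvalues Numeric p-values in \\[0, 1\\].
#' @param alpha Family-wise level (default 0.05).
#' @param m Family size (default the number of p-values supplied).
#' @return List with `alpha_adjusted` (`alpha/m`) and logical `significant`
#'   flags.
#' @export
bonferroni <- function(pvalues, alpha = 0.05, m = length(pvalues)) {
  if (length(pvalues) == 0) {
    return(list(alpha_adjusted = numeric(0), significant = logical(0)))
  }
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stopf("p-values must lie in [0, 1]")
  }
  list(alpha_adjusted = alpha / m, significant = !is.na(pvalues) & pvalues < alpha / m)
}

#' Whole-pipeline permutation test
#'
#' Forms the empirical null of a model-fit statistic by shuffling the case
#' labels (preserving the group sizes) `B` times and re-running the entire
#' analysis procedure on each permuted dataset. The empirical p-value uses
#' the add-one convention `p = (1 + #\{null >= observed\}) / (B + 1)`, so it
#' is never exactly zero. A permutation in which the statistic cannot be
#' computed (for example, every feature screened out) contributes the
#' chance value 0.5 and is logged.
#'
#' @param statistic Function taking a (permuted) label vector and returning
#'   a scalar model-fit statistic — typically a closure running screening
#'   plus cross-validated stepwise selection and returning the mean testing
#'   AUC.
#' @param y The observed binary labels.
#' @param B Number of permutations (default 199).
#' @param seed Optional seed for the permutation stream.
#' @return Object of class `perm_test` with `observed`, `null` (length-B
#'   vector), `B`, `p.value`, `n_failed`.
#' @export
permutation_test <- function(statistic, y, B = 199, seed = NULL) {
  if (B < 1) stopf("'B' must be at least 1")
  y <- coerce_binary(y)
  observed <- statistic(y)
  failed <- 0L
  null <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      yp <- sample(y)
      tryCatch(statistic(yp), error = function(e) {
        failed <<- failed + 1L
        0.5
      })
    }, numeric(1))
  })
  structure(list(observed = observed, null = null, B = B,
                 p.value = (1 + sum(null >= observed)) / (B + 1),
                 n_failed = failed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test: observed %.4f vs %d permutations, p = %.4g%s\n",
              x$observed, x$B, x$p.value,
              if (x$n_failed) sprintf(" (%d failed permutations scored 0.5)", x$n_failed)
              else ""))
  invisible(x)
}

#' Group-wise distribution summary with outlier flagging
#'
#' Median and quartiles per group, with outliers flagged at more than 1.5
#' interquartile ranges from the median (`convention = "median"`, the
#' study's definition) or outside the usual Tukey fences drawn from the
#' quartiles (`convention = "tukey"`).
#'
#' @param values Numeric vector.
#' @param groups Group labels aligned with `values`.
#' @param convention `"median"` (default) or `"tukey"`.
#' @return data.frame with one row per group: `median`, `q1`, `q3`,
#'   `fence_low`, `fence_high`, `n_outliers`, and an `outliers` list-column
#'   of flagged values.
#' @export
distribution_summary <- function(values, groups,
                                 convention = c("median", "tukey")) {
  convention <- match.arg(convention)
  groups <- as.factor(groups)
  if (any(tapply(!is.na(values), groups, sum) == 0)) stopf("empty group")
  rows <- lapply(levels(groups), function(g) {
    v <- values[groups == g & !is.na(values)]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    fence <- if (convention == "median") c(q[2] - 1.5 * iqr, q[2] + 1.5 * iqr)
             else c(q[1] - 1.5 * iqr, q[3] + 1.5 * iqr)
    out <- v[v < fence[1] | v > fence[2]]
    data.frame(group = g, n = length(v), median = q[2], q1 = q[1], q3 = q[3],
               fence_low = fence[1], fence_high = fence[2],
               n_outliers = length(out),
               outliers = I(list(out)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
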