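#' Detection filter: keep features observed in enough samples per group
#'
#' GC-TOF features are only reported when present in at least a threshold
#' fraction of samples of a study design group. A feature is kept when its
#' non-missing fraction reaches `threshold` in at least one diagnosis group
#' (`scope = "any"`, the default, so a case-only metabolite survives), or in
#' every group (`scope = "all"`).
#'
#' @param x A [feature_matrix()].
#' @param groups Factor of group labels aligned with the rows of `x`.
#' @param threshold Minimum non-missing fraction (default 0.5).
#' @param scope `"any"` or `"all"` group rule.
#' @return List with the filtered `matrix` and a `report` data.frame of
#'   per-feature per-group detection fractions and the keep decision.
#' @export
detection_filter <- function(x, groups, threshold = 0.5,
                             scope = c("any", "all")) {
  scope <- match.arg(scope)
  groups <- as.factor(groups)
  if (length(groups) != nrow(x$values)) {
    stopf("'groups' must be aligned with the rows of 'x'")
  }
  if (any(table(groups) == 0)) stopf("empty group in detection filter")
  frac <- t(apply(!is.na(x$values), 2, function(p) tapply(p, groups, mean)))
  keep <- if (scope == "any") apply(frac >= threshold, 1, any)
          else apply(frac >= threshold, 1, all)
  report <- data.frame(feature_id = feature_ids(x), frac,
                       kept = keep, row.names = NULL, check.names = FALSE)
  list(matrix = subset_features(x, which(keep)), report = report)
}

#' Normalize each sample to the summed intensity of known metabolites
#'
#' Divides every value by its sample's total intensity over features flagged
#' as known compounds (computed over non-missing entries), the standard
#' total-signal correction for GC-TOF peak tables.
#'
#' @param x A [feature_matrix()] with at least one known feature.
#' @return List with the normalized `matrix` and the per-sample `divisors`.
#' @export
sum_normalize <- function(x) {
  if (!any(x$known)) stopf("no known features to normalize against")
  div <- rowSums(x$values[, x$known, drop = FALSE], na.rm = TRUE)
  bad <- which(!is.finite(div) | div <= 0)
  if (length(bad)) {
    stopf("sample '%s' has no positive known-feature intensity",
          sample_ids(x)[bad[1]])
  }
  list(matrix = set_values(x, x$values / div), divisors = div)
}

#' Express ECA features relative to the pooled CSF reference
#'
#' Rescales each feature to percent of the pool reference value (pool taken
#' as 100), the quantification convention of the electrochemical-array
#' platform.
#'
#' @param x A [feature_matrix()] carrying `pool_reference`.
#' @return The rescaled `feature_matrix`.
#' @export
relative_to_pool <- function(x) {
  if (is.null(x$pool_reference)) stopf("no pool_reference available")
  if (any(!is.finite(x$pool_reference)) || any(x$pool_reference <= 0)) {
    stopf("pool_reference must be positive for every feature")
  }
  set_values(x, sweep(x$values, 2, x$pool_reference / 100, "/"))
}

#' Natural-log transform a feature matrix
#'
#' @param x A [feature_matrix()] whose present values are all positive.
#' @return The transformed `feature_matrix`; missingness is preserved.
#' @export
log_transform <- function(x) {
  bad <- which(x$values <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("non-positive value at sample '%s', feature '%s'",
          sample_ids(x)[bad[1, 1]], feature_ids(x)[bad[1, 2]])
  }
  set_values(x, log(x$values))
}

#' Impute missing values with half the feature minimum
#'
#' Logistic model fitting needs complete rows; remaining missing entries
#' (after the detection filter) are replaced by half the smallest observed
#' value of the feature, a conventional stand-in for below-detection peaks.
#' Apply before [log_transform()].
#'
#' @param x A [feature_matrix()].
#' @return The completed `feature_matrix`.
#' @export
impute_halfmin <- function(x) {
  v <- x$values
  for (j in seq_len(ncol(v))) {
    miss <- is.na(v[, j])
    if (!any(miss)) next
    if (all(miss)) stopf("feature '%s' has no observed values", feature_ids(x)[j])
    v[miss, j] <- min(v[, j], na.rm = TRUE) / 2
  }
  set_values(x, v)
}

#' Quantile-quantile normality diagnostic
#'
#' Correlation between the sample order statistics and standard-normal
#' quantiles at probability points (i - 0.5)/n; values near 1 indicate the
#' marginal distribution is close to Gaussian. Optionally writes a QQ plot.
#'
#' @param values Numeric vector (at least 3 non-missing values).
#' @param plot_file Optional path for a PNG QQ plot.
#' @return The quantile correlation (scalar).
#' @export
qq_normality <- function(values, plot_file = NULL) {
  v <- sort(values[!is.na(values)])
  n <- length(v)
  if (n < 3) stopf("need at least 3 non-missing values")
  if (stats::sd(v) == 0) stopf("constant vector: quantile correlation undefined")
  q <- stats::qnorm((seq_len(n) - 0.5) / n)
  r <- stats::cor(v, q)
  if (!is.null(plot_file)) {
    grDevices::png(plot_file, width = 500, height = 500)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::plot(q, v, xlab = "Standard normal quantiles",
                   ylab = "Sample quantiles",
                   main = sprintf("QQ normality, r = %.3f", r))
    graphics::abline(stats::lm(v ~ q), col = "grey40")
  }
  r
}

#' Run the full platform-specific preprocessing chain
#'
#' ECA: pool-relative scaling then log transform. GC-TOF: detection filter
#' against the diagnosis groups, sum normalization over known metabolites,
#' half-minimum imputation of the remaining missing peaks, then log
#' transform. Proteins: log transform only.
#'
#' @param matrices Named list of [feature_matrix()] objects as produced by
#'   [generate_cohort()] or [read_cohort()].
#' @param cohort Metadata data.frame with a `diagnosis` column.
#' @param detection_threshold,detection_scope Passed to [detection_filter()].
#' @param impute `"halfmin"` (default) or `"none"`.
#' @return List with `matrices` (log-scale, complete except when
#'   `impute = "none"`) and a `report` of drops and divisors.
#' @export
preprocess_cohort <- function(matrices, cohort, detection_threshold = 0.5,
                              detection_scope = "any",
                              impute = c("halfmin", "none")) {
  impute <- match.arg(impute)
  report <- list()
  out <- matrices
  if (!is.null(out$ECA)) {
    out$ECA <- log_transform(relative_to_pool(out$ECA))
    report$eca_transform <- "relative_to_pool + log"
  }
  if (!is.null(out$GCTOF)) {
    df <- detection_filter(out$GCTOF, cohort$diagnosis,
                           detection_threshold, detection_scope)
    sn <- sum_normalize(df$matrix)
    m <- sn$matrix
    if (impute == "halfmin") m <- impute_halfmin(m)
    out$GCTOF <- log_transform(m)
    report$gctof_detection <- df$report
    report$gctof_divisors <- sn$divisors
    report$gctof_transform <- "detection_filter + sum_normalize + impute + log"
  }
  if (!is.null(out$PROTEIN)) {
    out$PROTEIN <- log_transform(out$PROTEIN)
    report$protein_transform <- "log"
  }
  list(matrices = out, report = report)
}
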