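#' Two-sided Fisher's exact test for a 2 x 2 table
#'
#' Exact two-sided p-value obtained by summing the probabilities of all
#' tables with the observed margins whose hypergeometric probability does
#' not exceed that of the observed table, together with the conditional
#' maximum-likelihood odds ratio.
#'
#' @param table 2 x 2 matrix (or vector of length 4, filled by row) of
#'   non-negative integer counts with both margins positive.
#' @return List with `p.value`, `odds_ratio`, and the input `table`.
#' @examples
#' fisher_exact_2x2(matrix(c(6, 34, 0, 38), 2, byrow = TRUE))$p.value
#' @export
fisher_exact_2x2 <- function(table) {
  if (!is.matrix(table)) table <- matrix(table, 2, 2, byrow = TRUE)
  if (any(dim(table) != c(2, 2))) stopf("'table' must be 2 x 2")
  if (any(!is.finite(table)) || any(table < 0) || any(table != round(table))) {
    stopf("counts must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stopf("both margins must be positive")
  }
  ft <- stats::fisher.test(table)
  list(p.value = ft$p.value, odds_ratio = unname(ft$estimate), table = table)
}

#' Two-sample t test
#'
#' Welch's unequal-variance test by default; set `pooled = TRUE` for the
#' classical equal-variance form.
#'
#' @param x,y Numeric vectors (at least 2 non-missing values each).
#' @param pooled Use the pooled-variance statistic.
#' @return List with `statistic`, `df`, `p.value`.
#' @export
two_sample_t <- function(x, y, pooled = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stopf("need at least 2 values per group")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(statistic = 0, df = length(x) + length(y) - 2, p.value = 1))
    }
    stopf("zero variance in both groups with unequal means")
  }
  tt <- stats::t.test(x, y, var.equal = pooled)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value)
}

#' Kruskal-Wallis rank test
#'
#' Midrank-based H statistic with tie correction and a chi-square reference
#' with (number of groups - 1) degrees of freedom. When every value is tied
#' the statistic is 0 and p is 1 by convention.
#'
#' @param values Numeric vector.
#' @param groups Group labels aligned with `values`.
#' @return List with `statistic`, `df`, `p.value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2) stopf("need at least 2 groups")
  if (length(unique(values)) == 1) {
    return(list(statistic = 0, df = nlevels(groups) - 1, p.value = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value)
}

#' Pearson correlation with a t-based p-value
#'
#' @param x,y Paired numeric vectors with at least 3 complete pairs and
#'   non-degenerate variance.
#' @return List with `estimate`, `statistic`, `df`, `p.value`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stopf("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("constant input")
  ct <- stats::cor.test(x, y)
  list(estimate = unname(ct$estimate), statistic = unname(ct$statistic),
       df = unname(ct$parameter), p.value = ct$p.value)
}

#' Demographic and clinical comparison table
#'
#' The standard cohort-description table: Welch t tests for age, education
#' and MMSE; Fisher's exact tests for sex, race and each drug-class flag
#' against diagnosis.
#'
#' @param cohort Metadata data.frame as produced by [generate_cohort()].
#' @return data.frame with per-characteristic case/control summaries, the
#'   test used (`T` or `F`) and its p-value.
#' @export
demographics_table <- function(cohort) {
  case <- cohort$diagnosis == "case"
  rows <- list()
  for (v in c("age", "education", "mmse")) {
    if (!v %in% names(cohort)) next
    tt <- two_sample_t(cohort[[v]][case], cohort[[v]][!case])
    rows[[v]] <- data.frame(
      characteristic = v,
      case = sprintf("%.1f +/- %.1f", mean(cohort[[v]][case]), stats::sd(cohort[[v]][case])),
      control = sprintf("%.1f +/- %.1f", mean(cohort[[v]][!case]), stats::sd(cohort[[v]][!case])),
      test = "T", p.value = tt$p.value, stringsAsFactors = FALSE)
  }
  fisher_row <- function(label, flag) {
    tab <- matrix(c(sum(flag & case), sum(!flag & case),
                    sum(flag & !case), sum(!flag & !case)), 2)
    data.frame(characteristic = label,
               case = sprintf("%.1f%%", 100 * mean(flag[case])),
               control = sprintf("%.1f%%", 100 * mean(flag[!case])),
               test = "F", p.value = fisher_exact_2x2(tab)$p.value,
               stringsAsFactors = FALSE)
  }
  if ("sex" %in% names(cohort)) {
    rows$male <- fisher_row("male", cohort$sex == "male")
  }
  if ("race" %in% names(cohort)) {
    rows$caucasian <- fisher_row("caucasian", cohort$race == "caucasian")
  }
  for (d in intersect(DRUG_CLASSES, names(cohort))) {
    flag <- cohort[[d]]
    if (!any(flag)) {
      rows[[d]] <- data.frame(characteristic = d, case = "0.0%",
                              control = "0.0%", test = "F", p.value = 1,
                              stringsAsFactors = FALSE)
    } else {
      rows[[d]] <- fisher_row(d, flag)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
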