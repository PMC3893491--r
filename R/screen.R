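# Vectorized rank tests over the columns of a feature matrix, plus the
# drug/ApoE confound screen built on them.

tie_term <- function(v) {
  t <- tabulate(match(v, unique(v)))
  sum(t^3 - t)
}

# Kruskal-Wallis H and p for every column of X against grouping g.
kw_columns <- function(X, g) {
  g <- as.factor(g)
  if (nlevels(g) < 2) stopf("need at least 2 groups")
  N <- nrow(X)
  k <- nlevels(g)
  ng <- tabulate(g)
  R <- apply(X, 2, rank)
  if (is.null(dim(R))) R <- matrix(R, N, ncol(X))
  Rsum2 <- matrix(0, 1, ncol(X))
  H <- -3 * (N + 1) + (12 / (N * (N + 1))) *
    Reduce(`+`, lapply(seq_len(k), function(i) {
      colSums(R[g == levels(g)[i], , drop = FALSE])^2 / ng[i]
    }))
  ties <- apply(X, 2, tie_term)
  corr <- 1 - ties / (N^3 - N)
  H <- ifelse(corr <= 0, 0, H / corr)
  H <- pmax(H, 0)
  p <- ifelse(H == 0 & corr <= 0, 1, stats::pchisq(H, k - 1, lower.tail = FALSE))
  list(statistic = H, df = k - 1, p.value = p)
}

# Stratified two-group rank test (van Elteren): within each stratum where
# the flag varies, a tie-corrected Wilcoxon rank-sum centered and scaled by
# the stratum size, combined across strata and referred to chi-square(1).
# Used to test metabolite-drug and metabolite-genotype association while
# holding diagnosis fixed, so that a genuine disease marker is not mistaken
# for a confound of a case-exclusive treatment.
stratified_rank_columns <- function(X, flag, strata) {
  strata <- as.factor(strata)
  flag <- as.logical(flag)
  p <- ncol(X)
  Tnum <- numeric(p)
  Vden <- numeric(p)
  used <- FALSE
  for (s in levels(strata)) {
    idx <- which(strata == s)
    f <- flag[idx]
    if (length(unique(f)) < 2) next
    used <- TRUE
    Xs <- X[idx, , drop = FALSE]
    ns <- length(idx); n1 <- sum(f); n0 <- ns - n1
    R <- apply(Xs, 2, rank)
    if (is.null(dim(R))) R <- matrix(R, ns, p)
    W <- colSums(R[f, , drop = FALSE])
    E <- n1 * (ns + 1) / 2
    ties <- apply(Xs, 2, tie_term)
    Var <- n1 * n0 / 12 * ((ns + 1) - ties / (ns * (ns - 1)))
    Tnum <- Tnum + (W - E) / (ns + 1)
    Vden <- Vden + Var / (ns + 1)^2
  }
  if (!used) return(list(statistic = rep(NA_real_, p), df = 1,
                         p.value = rep(NA_real_, p)))
  Z2 <- ifelse(Vden > 0, Tnum^2 / Vden, 0)
  pval <- ifelse(Vden > 0, stats::pchisq(Z2, 1, lower.tail = FALSE), 1)
  list(statistic = Z2, df = 1, p.value = pval)
}

#' Screen metabolite features for drug and ApoE confounding
#'
#' Reproduces the pre-modeling confound filter: (1) drug classes nominally
#' associated with diagnosis are identified by Fisher's exact test; (2) for
#' each such drug, every metabolite is rank-tested against the drug flag;
#' (3) every metabolite is rank-tested against the binary ApoE risk grouping
#' (E3/E4 and E4/E4 high risk); (4) any metabolite with any confound p-value
#' below `alpha` is removed. Protein analytes are never screened.
#'
#' With the default `scope = "stratified"` the rank tests are computed
#' within diagnosis strata (a stratified Wilcoxon combined across strata).
#' Because the AD treatment drugs are used almost exclusively by cases, a
#' pooled test of metabolite versus drug flag is confounded with diagnosis
#' itself and would remove genuine disease markers; the stratified form
#' tests drug and genotype association at fixed disease status.
#' `scope = "pooled"` gives the plain pooled Kruskal-Wallis test instead.
#'
#' @param matrices Named list of log-scale, complete [feature_matrix()]
#'   objects; entries with platform `"PROTEIN"` are passed through.
#' @param cohort Metadata data.frame with `diagnosis`, the drug-class flags
#'   and `apoe_risk`.
#' @param alpha Nominal screening level (default 0.05).
#' @param scope `"stratified"` (default) or `"pooled"` rank tests.
#' @param union Test the union flag "uses any diagnosis-associated drug"
#'   instead of each drug separately.
#' @return An object of class `screen_report`; see Details.
#' @details The report carries the drug-diagnosis Fisher table
#'   (`drug_diagnosis`), the per-feature p-value matrix for the tested drugs
#'   (`drug_p`), the ApoE p-values (`apoe_p`), the removal table (`removed`,
#'   with reasons `"drug"`, `"apoe"` or both), counts `n_removed_drug`,
#'   `n_removed_apoe` and `n_remaining`, and `kept`, the retained feature
#'   ids per platform (screened metabolite platforms reduced, protein
#'   platforms untouched).
#' @export
screen_confounds <- function(matrices, cohort, alpha = 0.05,
                             scope = c("stratified", "pooled"),
                             union = FALSE) {
  scope <- match.arg(scope)
  metab <- matrices[vapply(matrices, function(m) m$platform != "PROTEIN", logical(1))]
  if (!length(metab)) stopf("no metabolite platform to screen")
  X <- do.call(cbind, lapply(metab, function(m) m$values))
  if (anyNA(X)) {
    stopf("screening requires complete matrices; impute missing values first")
  }
  diagnosis <- cohort$diagnosis
  case <- diagnosis == "case"

  # (1) which drugs are associated with diagnosis
  drug_rows <- list()
  for (d in intersect(DRUG_CLASSES, names(cohort))) {
    flag <- as.logical(cohort[[d]])
    if (length(unique(flag)) < 2) {
      warnf("drug '%s' is constant in the cohort; skipped", d)
      next
    }
    tab <- matrix(c(sum(flag & case), sum(!flag & case),
                    sum(flag & !case), sum(!flag & !case)), 2)
    ft <- fisher_exact_2x2(tab)
    drug_rows[[d]] <- data.frame(drug = d, p.value = ft$p.value,
                                 odds_ratio = ft$odds_ratio,
                                 associated = ft$p.value < alpha,
                                 stringsAsFactors = FALSE)
  }
  drug_diagnosis <- if (length(drug_rows)) do.call(rbind, drug_rows) else
    data.frame(drug = character(0), p.value = numeric(0),
               odds_ratio = numeric(0), associated = logical(0))
  rownames(drug_diagnosis) <- NULL
  assoc_drugs <- drug_diagnosis$drug[drug_diagnosis$associated]

  rank_test <- function(flag) {
    if (scope == "stratified") {
      stratified_rank_columns(X, flag, diagnosis)$p.value
    } else {
      kw_columns(X, factor(flag))$p.value
    }
  }

  # (2) metabolite vs diagnosis-associated drug use
  drug_p <- NULL
  if (length(assoc_drugs)) {
    if (union) {
      uflag <- Reduce(`|`, lapply(assoc_drugs, function(d) as.logical(cohort[[d]])))
      drug_p <- matrix(rank_test(uflag), ncol = 1,
                       dimnames = list(colnames(X), "any_associated_drug"))
    } else {
      drug_p <- vapply(assoc_drugs,
                       function(d) rank_test(as.logical(cohort[[d]])),
                       numeric(ncol(X)))
      drug_p <- matrix(drug_p, nrow = ncol(X),
                       dimnames = list(colnames(X), assoc_drugs))
    }
  }

  # (3) metabolite vs ApoE risk grouping
  apoe_p <- rep(NA_real_, ncol(X))
  names(apoe_p) <- colnames(X)
  if ("apoe_risk" %in% names(cohort) &&
      length(unique(cohort$apoe_risk)) > 1) {
    apoe_p[] <- rank_test(cohort$apoe_risk == "high")
  } else {
    warnf("ApoE risk grouping constant or absent; ApoE screen skipped")
  }

  # (4) removal
  drug_hit <- if (is.null(drug_p)) rep(FALSE, ncol(X)) else
    apply(drug_p < alpha, 1, any)
  drug_hit[is.na(drug_hit)] <- FALSE
  apoe_hit <- !is.na(apoe_p) & apoe_p < alpha
  sel <- drug_hit | apoe_hit
  removed_ids <- colnames(X)[sel]
  removed <- data.frame(
    feature_id = removed_ids,
    reason = ifelse(drug_hit[sel] & apoe_hit[sel], "drug;apoe",
                    ifelse(drug_hit[sel], "drug", "apoe")),
    stringsAsFactors = FALSE)

  kept <- lapply(matrices, function(m) {
    if (m$platform == "PROTEIN") feature_ids(m)
    else setdiff(feature_ids(m), removed_ids)
  })

  structure(list(drug_diagnosis = drug_diagnosis,
                 drugs_tested = assoc_drugs,
                 drug_p = drug_p, apoe_p = apoe_p,
                 removed = removed,
                 n_removed_drug = sum(drug_hit),
                 n_removed_apoe = sum(apoe_hit),
                 n_remaining = ncol(X) - length(removed_ids),
                 kept = kept, alpha = alpha, scope = scope, union = union),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %s scope, alpha = %g\n", x$scope, x$alpha))
  cat(sprintf("  diagnosis-associated drugs: %s\n",
              if (length(x$drugs_tested)) paste(x$drugs_tested, collapse = ", ")
              else "(none)"))
  cat(sprintf("  removed %d metabolites (%d drug-associated, %d ApoE-associated); %d remain\n",
              nrow(x$removed), x$n_removed_drug, x$n_removed_apoe, x$n_remaining))
  invisible(x)
}

#' Assemble the screened predictor matrix for a variable-set label
#'
#' Labels follow the published shorthand: `E` = ECA metabolites, `M` =
#' GC-TOF metabolites, `P` = protein analytes, joined with `|` for
#' combinations (e.g. `"P|M|E"`). Metabolite platforms are restricted to
#' the features retained by the screen; proteins are never screened.
#'
#' @param matrices Named list of preprocessed [feature_matrix()] objects.
#' @param screen A [screen_confounds()] report, or `NULL` to skip screening.
#' @param pools A single label string.
#' @return Numeric predictor matrix (samples by features).
#' @export
pool_matrix <- function(matrices, screen, pools) {
  map <- c(E = "ECA", M = "GCTOF", P = "PROTEIN")
  parts <- lapply(strsplit(pools, "|", fixed = TRUE)[[1]], function(lab) {
    pf <- map[[lab]]
    m <- matrices[[pf]]
    if (is.null(m)) stopf("platform '%s' not available for pool '%s'", pf, pools)
    keep <- if (is.null(screen)) feature_ids(m) else screen$kept[[pf]]
    m$values[, keep, drop = FALSE]
  })
  do.call(cbind, parts)
}
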