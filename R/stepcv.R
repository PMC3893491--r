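#' Forward stepwise logistic regression under BIC
#'
#' Starting from the intercept-only model, fits every single-feature
#' addition, adds the feature with the lowest BIC if it is strictly lower
#' than the current model's BIC, and stops otherwise. Ties are broken
#' deterministically by feature id order; candidate fits flagged for
#' quasi-complete separation are skipped.
#'
#' @param x Numeric predictor matrix (samples by features, complete).
#' @param y Binary outcome.
#' @param candidates Feature ids eligible for selection (default all
#'   columns of `x`).
#' @param max_steps Cap on the number of additions.
#' @return A `logistic_fit` for the selected model, with an extra element
#'   `selected` (feature ids in order of entry) and `path` (data.frame of
#'   the BIC trajectory).
#' @export
forward_stepwise_bic <- function(x, y, candidates = colnames(x),
                                 max_steps = Inf) {
  y <- coerce_binary(y)
  cur <- fit_logistic(NULL, y)
  selected <- character(0)
  path <- list(data.frame(step = 0L, feature = "(Intercept)", bic = cur$bic))
  if (!is.null(x)) x <- as.matrix(x)
  repeat {
    rem <- setdiff(candidates, selected)
    if (!length(rem) || length(selected) >= max_steps) break
    xc <- cbind(1, x[, selected, drop = FALSE])
    sc <- scan_add1(xc, y, cur$coefficients, x[, rem, drop = FALSE])
    bics <- ifelse(sc$separated, Inf, sc$bic)
    best <- min(bics)
    if (!is.finite(best) || best >= cur$bic - 1e-8) break
    cand <- rem[bics <= best + 1e-8]
    pick <- sort(cand)[1]
    new_sel <- c(selected, pick)
    warm <- c(cur$coefficients, 0)
    refit <- fit_logistic(x[, new_sel, drop = FALSE], y, start = warm)
    if (refit$separated || refit$bic >= cur$bic - 1e-8) break
    selected <- new_sel
    cur <- refit
    path[[length(path) + 1]] <- data.frame(step = length(selected),
                                           feature = pick, bic = cur$bic)
  }
  cur$selected <- selected
  cur$path <- do.call(rbind, path)
  cur
}

#' Stratified cross-validation folds
#'
#' Partitions the samples into `K` folds with class proportions per fold
#' within one sample of the overall proportion, seeded and reproducible.
#'
#' @param y Binary outcome.
#' @param K Number of folds (default 5).
#' @param seed Optional integer seed.
#' @return Integer fold assignment (1..K) per sample.
#' @export
make_folds <- function(y, K = 5, seed = NULL) {
  y <- coerce_binary(y)
  n <- length(y)
  if (n < K) stopf("need at least K samples")
  if (min(sum(y), n - sum(y)) < K) stopf("each class must have at least K samples")
  with_seed(seed, {
    folds <- integer(n)
    for (cls in c(0, 1)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(K), length(idx)))
    }
    folds
  })
}

#' Per-fold stepwise model building
#'
#' Runs [forward_stepwise_bic()] on each 4/5 training portion, recording the
#' per-fold model, its training AUC, the testing AUC on the held-out fifth,
#' the out-of-fold predicted probability of every sample, and how many folds
#' selected each feature (the cross-validation consistency counts).
#' Confound screening is applied once, before this function (the study's
#' sequence); it is not re-run inside folds.
#'
#' @param x Screened, complete predictor matrix.
#' @param y Binary outcome.
#' @param K Number of folds.
#' @param seed Seed for the fold assignment.
#' @param folds Optional explicit fold assignment (overrides `K`/`seed`).
#' @return An object of class `cvrun`.
#' @export
cross_validated_selection <- function(x, y, K = 5, seed = NULL, folds = NULL) {
  y <- coerce_binary(y)
  x <- as.matrix(x)
  if (is.null(folds)) folds <- make_folds(y, K, seed) else K <- max(folds)
  counts <- stats::setNames(integer(ncol(x)), colnames(x))
  models <- vector("list", K)
  train_auc <- test_auc <- numeric(K)
  oof <- rep(NA_real_, length(y))
  for (k in seq_len(K)) {
    tr <- folds != k
    fit <- forward_stepwise_bic(x[tr, , drop = FALSE], y[tr])
    models[[k]] <- fit
    counts[fit$selected] <- counts[fit$selected] + 1L
    train_auc[k] <- auc(fit$fitted, y[tr])
    pred <- predict_logistic(fit, x[!tr, , drop = FALSE])
    oof[!tr] <- pred
    test_auc[k] <- auc(pred, y[!tr])
  }
  structure(list(folds = folds, models = models, train_auc = train_auc,
                 test_auc = test_auc, mean_test_auc = mean(test_auc),
                 selection_counts = counts, oof_pred = oof, y = y, K = K,
                 seed = seed),
            class = "cvrun")
}

#' @export
print.cvrun <- function(x, ...) {
  cat(sprintf("<cvrun> K = %d; mean training AUC %.3f, mean testing AUC %.3f\n",
              x$K, mean(x$train_auc), x$mean_test_auc))
  sel <- sort(x$selection_counts[x$selection_counts > 0], decreasing = TRUE)
  if (length(sel)) {
    cat("  selection counts:",
        paste(sprintf("%s (%d/%d)", names(sel), sel, x$K), collapse = ", "), "\n")
  } else cat("  no feature selected in any fold\n")
  invisible(x)
}

#' Consistency-based final variable selection
#'
#' Returns the features selected in at least `threshold` of the K per-fold
#' stepwise models (default the majority, 3 of 5). If no feature reaches
#' the threshold, the feature(s) with the maximal selection count are
#' returned instead — the literal "selected in the most cross-validation
#' models" rule — with ties retained jointly. An all-zero count table gives
#' the empty set.
#'
#' @param cvrun A [cross_validated_selection()] result.
#' @param threshold Minimum number of folds (default `ceiling(K/2)`).
#' @return Character vector of feature ids.
#' @export
consistency_select <- function(cvrun, threshold = ceiling(cvrun$K / 2)) {
  counts <- cvrun$selection_counts
  hit <- names(counts)[counts >= threshold]
  if (length(hit)) return(sort(hit))
  mx <- max(counts)
  if (mx == 0) return(character(0))
  sort(names(counts)[counts == mx])
}

#' Refit the consistency-selected model on all samples
#'
#' The refit provides reportable coefficients (the analogue of a published
#' final model equation); the model's discrimination summary keeps the
#' cross-validated mean testing AUC, not the refit's apparent AUC. A refit
#' that separates is stabilized with a 1e-6 ridge for reporting only.
#'
#' @param x Predictor matrix.
#' @param y Binary outcome.
#' @param features Consistency-selected feature ids (possibly empty).
#' @return A `logistic_fit` (intercept-only when `features` is empty).
#' @export
fit_final_model <- function(x, y, features) {
  if (!length(features)) return(fit_logistic(NULL, coerce_binary(y)))
  fit <- fit_logistic(x[, features, drop = FALSE], y)
  if (fit$separated) {
    fit <- fit_logistic(x[, features, drop = FALSE], y, ridge = 1e-6)
    fit$separated <- TRUE
  }
  fit$selected <- features
  fit
}

#' Cross-validated stepwise logistic discrimination
#'
#' The package's central fitting function. Builds forward stepwise logistic
#' models under BIC on every 4/5 split of a stratified K-fold partition,
#' selects the final variables by cross-validation consistency, refits them
#' on all samples for coefficient reporting, and summarizes discrimination
#' by the mean testing AUC with sensitivity and specificity computed from
#' the pooled out-of-fold predicted probabilities at the 0.5 cutoff.
#'
#' @param x Numeric predictor matrix (samples by features), already
#'   preprocessed and screened.
#' @param y Binary outcome: 0/1, logical, or a two-level factor with the
#'   case level second.
#' @param K Number of cross-validation folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param threshold Consistency threshold in folds (default majority).
#' @param label Optional variable-set label (e.g. `"E"`, `"P|M"`).
#' @param cutoff Probability cutoff for sensitivity/specificity.
#' @return An object of class `stepcv` with components `cvrun` (per-fold
#'   models and AUCs), `selected`, `final_fit`, `mean_test_auc`,
#'   `sensitivity`, `specificity`.
#' @seealso [consistency_select()], [forward_stepwise_bic()],
#'   [permutation_test()], [delong_test()]
#' @examples
#' syn <- generate_cohort(cohort_config(seed = 7))
#' prep <- preprocess_cohort(syn$matrices, syn$cohort)
#' x <- prep$matrices$ECA$values
#' fit <- stepcv(x, syn$cohort$diagnosis, seed = 7)
#' fit
#' @export
stepcv <- function(x, y, K = 5, seed = NULL, threshold = ceiling(K / 2),
                   label = NULL, cutoff = 0.5) {
  y <- coerce_binary(y)
  x <- as.matrix(x)
  cv <- cross_validated_selection(x, y, K = K, seed = seed)
  selected <- consistency_select(cv, threshold)
  final <- fit_final_model(x, y, selected)
  ss <- sens_spec(cv$oof_pred, y, cutoff = cutoff)
  structure(list(cvrun = cv, selected = selected, final_fit = final,
                 mean_test_auc = cv$mean_test_auc,
                 sensitivity = as.numeric(ss$sensitivity),
                 specificity = as.numeric(ss$specificity),
                 threshold = threshold, label = label, cutoff = cutoff,
                 n = length(y), call = match.call()),
            class = "stepcv")
}

#' @export
print.stepcv <- function(x, ...) {
  cat(sprintf("Cross-validated stepwise logistic discrimination%s\n",
              if (!is.null(x$label)) sprintf(" [%s]", x$label) else ""))
  cat(sprintf("  n = %d, K = %d folds, consistency threshold %d\n",
              x$n, x$cvrun$K, x$threshold))
  if (length(x$selected)) {
    cat("  consistency-selected:",
        paste(sprintf("%s (%d/%d)", x$selected,
                      x$cvrun$selection_counts[x$selected], x$cvrun$K),
              collapse = ", "), "\n")
  } else cat("  consistency-selected: (intercept only)\n")
  cat(sprintf("  mean testing AUC %.3f; sensitivity %.2f, specificity %.2f at cutoff %.2f\n",
              x$mean_test_auc, x$sensitivity, x$specificity, x$cutoff))
  invisible(x)
}

#' @export
summary.stepcv <- function(object, ...) {
  cv <- object$cvrun
  folds <- data.frame(
    fold = seq_len(cv$K),
    selected = vapply(cv$models, function(m)
      if (length(m$selected)) paste(m$selected, collapse = "+") else "(intercept)",
      character(1)),
    train_auc = cv$train_auc,
    test_auc = cv$test_auc)
  structure(list(folds = folds,
                 selection_counts = sort(cv$selection_counts[cv$selection_counts > 0],
                                         decreasing = TRUE),
                 selected = object$selected,
                 coefficients = object$final_fit$coefficients,
                 mean_test_auc = object$mean_test_auc,
                 sensitivity = object$sensitivity,
                 specificity = object$specificity,
                 separated = object$final_fit$separated,
                 label = object$label),
            class = "summary.stepcv")
}

#' @export
print.summary.stepcv <- function(x, ...) {
  cat(sprintf("Per-fold stepwise models%s:\n",
              if (!is.null(x$label)) sprintf(" [%s]", x$label) else ""))
  print(x$folds, row.names = FALSE, digits = 3)
  cat(sprintf("\nMean testing AUC %.3f; sensitivity %.2f, specificity %.2f\n",
              x$mean_test_auc, x$sensitivity, x$specificity))
  cat("Final refit coefficients",
      if (x$separated) "(separated; ridge-stabilized):" else ":", "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.stepcv <- function(object, ...) object$final_fit$coefficients

#' @export
predict.stepcv <- function(object, newdata, type = c("response", "link"), ...) {
  predict_logistic(object$final_fit, as.matrix(newdata), match.arg(type))
}

#' @export
residuals.stepcv <- function(object, ...) {
  f <- object$final_fit
  y <- object$cvrun$y
  sign(y - f$fitted) * sqrt(-2 * (y * log(f$fitted) + (1 - y) * log(1 - f$fitted)))
}

#' @export
plot.stepcv <- function(x, ...) {
  rc <- roc_curve(x$cvrun$oof_pred, x$cvrun$y)
  graphics::plot(rc$fpr, rc$tpr, type = "s",
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 main = sprintf("Out-of-fold ROC%s (AUC %.3f)",
                                if (!is.null(x$label)) sprintf(" [%s]", x$label) else "",
                                rc$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(rc)
}
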