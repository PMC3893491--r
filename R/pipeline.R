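VALID_POOLS <- c("E", "M", "P", "P|E", "P|M", "E|M", "P|M|E")

#' Configuration of a full discrimination analysis run
#'
#' @param generator A [cohort_config()] describing the synthetic cohort, or
#'   `NULL` when `input` is given.
#' @param input Optional directory previously written by [write_cohort()].
#' @param pools Variable-set labels to model: subsets of `E` (ECA
#'   metabolites), `M` (GC-TOF metabolites), `P` (proteins) joined with
#'   `|`. Default: the six published combinations.
#' @param K Cross-validation folds.
#' @param B Permutations per model (default 199 for desk-scale runs; set
#'   1000 for the full analysis).
#' @param alpha Nominal screening level.
#' @param seed Master seed; all stage seeds derive from it and are echoed
#'   in the output.
#' @param consistency_threshold Folds required for consistency selection.
#' @param screen_scope `"stratified"` or `"pooled"` confound tests, see
#'   [screen_confounds()].
#' @param permute_rescreen Re-run the confound screen inside every
#'   permutation (the entire procedure is permuted; default `TRUE`).
#' @param detection_threshold,detection_scope,impute Preprocessing options,
#'   see [preprocess_cohort()].
#' @param cutoff Probability cutoff for sensitivity/specificity.
#' @return Object of class `run_config`.
#' @export
run_config <- function(generator = cohort_config(), input = NULL,
                       pools = c("E", "M", "P", "P|E", "P|M", "P|M|E"),
                       K = 5, B = 199, alpha = 0.05, seed = 1,
                       consistency_threshold = ceiling(K / 2),
                       screen_scope = "stratified",
                       permute_rescreen = TRUE,
                       detection_threshold = 0.5, detection_scope = "any",
                       impute = "halfmin", cutoff = 0.5) {
  if (!length(pools)) stopf("at least one pool must be requested")
  bad <- setdiff(pools, VALID_POOLS)
  if (length(bad)) {
    stopf("invalid pool label(s): %s (valid: %s)",
          paste(bad, collapse = ", "), paste(VALID_POOLS, collapse = ", "))
  }
  if (is.null(input) && is.null(generator)) {
    stopf("either a generator configuration or an input directory is required")
  }
  if (!is.null(input) && !dir.exists(input)) {
    stopf("input directory '%s' is not readable", input)
  }
  structure(list(generator = generator, input = input, pools = pools, K = K,
                 B = B, alpha = alpha, seed = seed,
                 consistency_threshold = consistency_threshold,
                 screen_scope = screen_scope,
                 permute_rescreen = permute_rescreen,
                 detection_threshold = detection_threshold,
                 detection_scope = detection_scope, impute = impute,
                 cutoff = cutoff),
            class = "run_config")
}

#' Run the full discrimination analysis
#'
#' Generates (or reads) the cohort, preprocesses each platform, screens
#' metabolites for drug and ApoE confounding, builds a cross-validated
#' stepwise logistic model for every requested variable-set combination,
#' assesses each model by whole-pipeline permutation, and compares all
#' model pairs with Bonferroni-corrected DeLong tests on the pooled
#' out-of-fold predictions.
#'
#' @param config A [run_config()].
#' @return Object of class `discrim_report`: `models` (data.frame, one row
#'   per pool: selected variables, mean testing AUC, sensitivity,
#'   specificity, permutation p), `fits` (the `stepcv` objects),
#'   `permutations`, `delong` (all-pairs comparison table with the
#'   Bonferroni mask), `screen`, `demographics`, `seeds`, `timings`.
#' @export
run_all <- function(config = run_config()) {
  if (!inherits(config, "run_config")) stopf("'config' must be a run_config()")
  t0 <- proc.time()[["elapsed"]]
  seeds <- list(cohort = child_seed(config$seed, 1),
                folds = child_seed(config$seed, 2),
                permutation = child_seed(config$seed, 3))
  timings <- c()
  tick <- function(stage) {
    t <- proc.time()[["elapsed"]]
    timings[[stage]] <<- t - t0
    t0 <<- t
  }

  if (!is.null(config$input)) {
    data <- read_cohort(config$input)
  } else {
    gen <- config$generator
    gen$seed <- seeds$cohort
    data <- generate_cohort(gen)
  }
  cohort <- data$cohort
  y <- coerce_binary(cohort$diagnosis)
  tick("data")

  prep <- preprocess_cohort(data$matrices, cohort,
                            detection_threshold = config$detection_threshold,
                            detection_scope = config$detection_scope,
                            impute = config$impute)
  tick("preprocess")

  screen <- screen_confounds(prep$matrices, cohort, alpha = config$alpha,
                             scope = config$screen_scope)
  tick("screen")

  fits <- list()
  for (pool in config$pools) {
    x <- pool_matrix(prep$matrices, screen, pool)
    fits[[pool]] <- stepcv(x, y, K = config$K, seed = seeds$folds,
                           threshold = config$consistency_threshold,
                           label = pool, cutoff = config$cutoff)
  }
  tick("models")

  perms <- list()
  for (pool in config$pools) {
    stat <- pipeline_statistic(prep$matrices, cohort, pool, config, seeds)
    perms[[pool]] <- permutation_test(stat, y, B = config$B,
                                      seed = child_seed(seeds$permutation,
                                                        match(pool, VALID_POOLS)))
  }
  tick("permutation")

  labels <- config$pools
  pairs <- if (length(labels) >= 2) utils::combn(labels, 2) else
    matrix(character(0), 2, 0)
  dl <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    dt <- delong_test(fits[[a]]$cvrun$oof_pred, fits[[b]]$cvrun$oof_pred, y)
    data.frame(model1 = a, model2 = b, auc1 = dt$auc1, auc2 = dt$auc2,
               z = dt$statistic, p.value = dt$p.value,
               stringsAsFactors = FALSE)
  })
  delong <- if (length(dl)) do.call(rbind, dl) else
    data.frame(model1 = character(0), model2 = character(0),
               auc1 = numeric(0), auc2 = numeric(0), z = numeric(0),
               p.value = numeric(0))
  bf <- bonferroni(delong$p.value, alpha = 0.05)
  delong$significant <- bf$significant
  attr(delong, "alpha_adjusted") <- bf$alpha_adjusted
  tick("delong")

  models <- do.call(rbind, lapply(labels, function(pool) {
    f <- fits[[pool]]
    data.frame(label = pool,
               n_offered = length(screened_pool_size(prep$matrices, screen, pool)),
               selected = if (length(f$selected))
                 paste(f$selected, collapse = "+") else "(intercept only)",
               auc = f$mean_test_auc,
               sensitivity = f$sensitivity, specificity = f$specificity,
               perm_p = perms[[pool]]$p.value,
               stringsAsFactors = FALSE)
  }))

  structure(list(models = models, fits = fits, permutations = perms,
                 delong = delong, screen = screen,
                 demographics = demographics_table(cohort),
                 preprocess = prep$report, config = config, seeds = seeds,
                 truth = data$truth, timings = timings),
            class = "discrim_report")
}

screened_pool_size <- function(matrices, screen, pool) {
  colnames(pool_matrix(matrices, screen, pool))
}

# Closure for the permutation null: optionally re-screens under the
# permuted labels, then reruns cross-validated stepwise selection, and
# returns the mean testing AUC (the pluggable model-fit statistic).
pipeline_statistic <- function(matrices, cohort, pool, config, seeds) {
  force(matrices); force(cohort); force(pool); force(config); force(seeds)
  function(y_perm) {
    coh <- cohort
    coh$diagnosis <- factor(ifelse(y_perm == 1, "case", "control"),
                            levels = c("control", "case"))
    scr <- if (config$permute_rescreen) {
      suppressWarnings(screen_confounds(matrices, coh, alpha = config$alpha,
                                        scope = config$screen_scope))
    } else {
      screen_confounds(matrices, cohort, alpha = config$alpha,
                       scope = config$screen_scope)
    }
    x <- pool_matrix(matrices, scr, pool)
    if (ncol(x) == 0) return(0.5)
    cv <- cross_validated_selection(x, y_perm, K = config$K,
                                    seed = seeds$folds)
    cv$mean_test_auc
  }
}

#' @export
print.discrim_report <- function(x, ...) {
  cat("Discrimination analysis report\n")
  cat(sprintf("  screen: %d metabolites removed, %d remaining\n",
              nrow(x$screen$removed), x$screen$n_remaining))
  print(x$models, row.names = FALSE, digits = 3)
  sig <- x$delong[x$delong$significant, , drop = FALSE]
  cat(sprintf("  DeLong: %d of %d pairs significant after Bonferroni\n",
              nrow(sig), nrow(x$delong)))
  invisible(x)
}

#' Render a human-readable report
#'
#' Markdown tables for the demographic comparison, the screening summary,
#' the per-model fit summaries and the pairwise DeLong comparisons (only
#' Bonferroni-significant pairs are listed in the matrix, mirroring the
#' published layout), plus optional box plots of the top
#' consistency-selected features.
#'
#' @param report A [run_all()] result.
#' @param path Optional directory; when given, writes `report.md`, the JSON
#'   bundle, and box-plot PNGs there.
#' @return The markdown text, invisibly when written to a file.
#' @export
render_report <- function(report, path = NULL) {
  for (stage in c("models", "delong", "screen", "demographics")) {
    if (is.null(report[[stage]])) stopf("incomplete bundle: missing '%s'", stage)
  }
  md <- c("# CSF biomarker discrimination report", "",
          "## Participant characteristics", "",
          md_table(transform(report$demographics,
                             p.value = signif(p.value, 3))),
          "", "## Confound screening", "",
          sprintf("- Diagnosis-associated drugs: %s",
                  if (length(report$screen$drugs_tested))
                    paste(report$screen$drugs_tested, collapse = ", ")
                  else "(none)"),
          sprintf("- Removed %d metabolites (%d drug-associated, %d ApoE-associated); %d remain",
                  nrow(report$screen$removed), report$screen$n_removed_drug,
                  report$screen$n_removed_apoe, report$screen$n_remaining),
          "", "## Model summaries", "",
          md_table(transform(report$models,
                             auc = round(auc, 3),
                             sensitivity = round(sensitivity, 2),
                             specificity = round(specificity, 2),
                             perm_p = signif(perm_p, 3))),
          "", "## Pairwise DeLong comparisons", "",
          sprintf("Bonferroni-adjusted alpha: %.4g (%d pairs). Only significant pairs listed.",
                  attr(report$delong, "alpha_adjusted") %||% NA,
                  nrow(report$delong)), "")
  sig <- report$delong[report$delong$significant, , drop = FALSE]
  md <- c(md, if (nrow(sig)) md_table(transform(sig, p.value = signif(p.value, 3),
                                                auc1 = round(auc1, 3),
                                                auc2 = round(auc2, 3),
                                                z = round(z, 2)))
          else "(no pair significant)")
  md <- c(md, "", "## Seeds", "",
          sprintf("- %s: %s", names(report$seeds),
                  unlist(report$seeds)))
  text <- paste(md, collapse = "\n")
  if (!is.null(path)) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    writeLines(text, file.path(path, "report.md"))
    report_to_json(report, file.path(path, "report.json"))
    plot_top_features(report, path)
    return(invisible(text))
  }
  text
}

md_table <- function(df) {
  df <- as.data.frame(lapply(df, function(col) {
    if (is.list(col)) vapply(col, function(v) paste(signif(v, 3), collapse = ";"),
                             character(1))
    else as.character(col)
  }), stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- names(df)
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  rows <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  c(header, sep, rows)
}

plot_top_features <- function(report, path) {
  sel <- unique(unlist(lapply(report$fits, function(f) f$selected)))
  if (!length(sel)) return(invisible(NULL))
  # recover the preprocessed values from the fits' design is not stored;
  # box plots use the out-of-fold predictions per model instead when the
  # raw features are unavailable.
  for (pool in names(report$fits)) {
    f <- report$fits[[pool]]
    fn <- file.path(path, sprintf("oof_%s.png", gsub("[|]", "-", pool)))
    grDevices::png(fn, width = 480, height = 480)
    graphics::boxplot(split(f$cvrun$oof_pred, f$cvrun$y),
                      names = c("control", "case"),
                      main = sprintf("Out-of-fold predicted probability [%s]", pool),
                      ylab = "P(case)")
    grDevices::dev.off()
  }
  invisible(NULL)
}

#' Serialize a report bundle to JSON
#'
#' @param report A [run_all()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
report_to_json <- function(report, path) {
  out <- list(
    models = report$models,
    delong = report$delong,
    alpha_adjusted = attr(report$delong, "alpha_adjusted"),
    screen = list(drug_diagnosis = report$screen$drug_diagnosis,
                  removed = report$screen$removed,
                  n_removed_drug = report$screen$n_removed_drug,
                  n_removed_apoe = report$screen$n_removed_apoe,
                  n_remaining = report$screen$n_remaining),
    demographics = report$demographics,
    seeds = report$seeds,
    selection_counts = lapply(report$fits, function(f)
      as.list(f$cvrun$selection_counts[f$cvrun$selection_counts > 0]))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
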