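# Delimited-text serialization of a cohort and its feature tables.
# Numeric cells are written with "%.17g" so doubles round-trip exactly;
# missing cells are written as empty fields and read back as NA.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

write_tsv_exact <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], fmt_num)
  out[!num] <- lapply(out[!num], function(col) {
    col <- as.character(col)
    col[is.na(col)] <- ""
    col
  })
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

#' Write a cohort and its feature tables to a directory
#'
#' Serializes the per-sample metadata, one TSV per platform (first column
#' `sample_id`, remaining columns the feature ids), a sidecar annotation
#' table (`feature_id`, `platform`, `known_flag`, `pool_reference`), and —
#' for synthetic cohorts — the planted ground truth as JSON. The round trip
#' through [read_cohort()] is lossless, including missing values.
#'
#' @param x A `synthetic_cohort`, or a list with elements `cohort` and
#'   `matrices` (and optionally `truth`).
#' @param path Directory to write into (created if absent).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_tsv_exact(x$cohort, file.path(path, "metadata.tsv"))
  ann <- do.call(rbind, lapply(x$matrices, function(m) {
    data.frame(feature_id = feature_ids(m), platform = m$platform,
               known_flag = m$known,
               pool_reference = if (is.null(m$pool_reference)) NA_real_ else m$pool_reference,
               stringsAsFactors = FALSE)
  }))
  write_tsv_exact(ann, file.path(path, "annotations.tsv"))
  for (m in x$matrices) {
    df <- data.frame(sample_id = sample_ids(m), as.data.frame(m$values),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv_exact(df, file.path(path, sprintf("features_%s.tsv", m$platform)))
  }
  if (!is.null(x$truth)) {
    truth <- x$truth
    # named vectors serialize as JSON objects so names survive the round trip
    truth$drug_confounded_features <- as.list(truth$drug_confounded_features)
    truth$effects <- as.list(truth$effects)
    jsonlite::write_json(truth, file.path(path, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "")
  if (names(df)[1] != "sample_id") {
    stopf("parse error in '%s': first column must be 'sample_id'", basename(path))
  }
  ids <- as.character(df$sample_id)
  if (anyDuplicated(ids)) {
    stopf("parse error in '%s': duplicated sample_id '%s'", basename(path),
          ids[duplicated(ids)][1])
  }
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(!is.na(col) & is.na(suppressWarnings(as.numeric(col))))[1]
      stopf("parse error in '%s': non-numeric cell at row %d, column '%s'",
            basename(path), bad, names(vals)[j])
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path Directory containing `metadata.tsv`, `annotations.tsv` and
#'   one `features_<PLATFORM>.tsv` per platform.
#' @return A list with elements `cohort`, `matrices`, and `truth` (or `NULL`
#'   when no truth file is present).
#' @export
read_cohort <- function(path) {
  meta_path <- file.path(path, "metadata.tsv")
  if (!file.exists(meta_path)) stopf("no metadata.tsv under '%s'", path)
  cohort <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                              na.strings = "")
  if (anyDuplicated(cohort$sample_id)) {
    stopf("parse error in 'metadata.tsv': duplicated sample_id '%s'",
          cohort$sample_id[duplicated(cohort$sample_id)][1])
  }
  cohort$diagnosis <- factor(cohort$diagnosis, levels = c("control", "case"))
  if ("sex" %in% names(cohort)) {
    cohort$sex <- factor(cohort$sex, levels = c("female", "male"))
  }
  if ("race" %in% names(cohort)) {
    cohort$race <- factor(cohort$race, levels = c("caucasian", "other"))
  }
  if ("apoe_risk" %in% names(cohort)) {
    cohort$apoe_risk <- factor(cohort$apoe_risk, levels = c("low", "high"))
  }
  ann <- utils::read.delim(file.path(path, "annotations.tsv"),
                           stringsAsFactors = FALSE, na.strings = "")
  matrices <- list()
  for (pf in unique(ann$platform)) {
    vals <- read_feature_table(file.path(path, sprintf("features_%s.tsv", pf)))
    a <- ann[ann$platform == pf, ]
    vals <- vals[, a$feature_id, drop = FALSE]
    pool <- if (all(is.na(a$pool_reference))) NULL else a$pool_reference
    matrices[[pf]] <- feature_matrix(vals, pf, as.logical(a$known_flag), pool)
  }
  truth_path <- file.path(path, "truth.json")
  truth <- NULL
  if (file.exists(truth_path)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    truth$drug_confounded_features <- unlist(truth$drug_confounded_features) %||%
      stats::setNames(character(0), character(0))
    truth$effects <- unlist(truth$effects)
  }
  list(cohort = cohort, matrices = matrices, truth = truth)
}
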