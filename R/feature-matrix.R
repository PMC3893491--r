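#' Construct a feature matrix for one measurement platform
#'
#' A `feature_matrix` bundles one platform's sample-by-feature table of
#' relative concentrations with its per-feature annotation: the platform
#' label, a known/unknown compound flag, and (for the electrochemical-array
#' platform, where analytes are quantified against a pooled CSF reference
#' run alongside the samples) the pool reference value of each feature.
#'
#' @param values Numeric matrix, samples in rows (rownames = sample ids),
#'   features in columns (colnames = feature ids). Missing entries are `NA`;
#'   present entries must be strictly positive so the table remains
#'   log-transformable.
#' @param platform One of `"ECA"`, `"GCTOF"`, `"PROTEIN"`.
#' @param known Logical vector, one flag per feature; identified compounds
#'   are `TRUE`, unknown spectral/electrochemical features `FALSE`.
#' @param pool_reference Numeric vector of per-feature pool values
#'   (required, and strictly positive, for `"ECA"`), or `NULL`.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, platform = c("ECA", "GCTOF", "PROTEIN"),
                           known = rep(TRUE, ncol(values)),
                           pool_reference = NULL) {
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("'values' needs sample ids as rownames and feature ids as colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stopf("duplicated sample id: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stopf("duplicated feature id: %s",
          paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  }
  if (length(known) != ncol(values)) stopf("'known' must have one flag per feature")
  if (any(values <= 0, na.rm = TRUE)) {
    bad <- which(values <= 0, arr.ind = TRUE)[1, ]
    stopf("non-positive value at sample '%s', feature '%s'",
          rownames(values)[bad[1]], colnames(values)[bad[2]])
  }
  if (platform == "ECA") {
    if (is.null(pool_reference)) stopf("ECA matrices require 'pool_reference'")
    if (length(pool_reference) != ncol(values)) {
      stopf("'pool_reference' must have one value per feature")
    }
    if (any(!is.finite(pool_reference)) || any(pool_reference <= 0)) {
      stopf("'pool_reference' must be positive for every feature")
    }
  }
  structure(
    list(values = values, platform = platform,
         known = as.logical(known),
         pool_reference = if (is.null(pool_reference)) NULL else as.numeric(pool_reference)),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> platform %s: %d samples x %d features (%d known, %.1f%% missing)\n",
              x$platform, nrow(x$values), ncol(x$values), sum(x$known),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

feature_ids <- function(x) colnames(x$values)
sample_ids <- function(x) rownames(x$values)

# Replace the value slot, keeping annotations aligned.
set_values <- function(x, values) {
  x$values <- values
  x
}

# Subset features of a feature_matrix by id or index.
subset_features <- function(x, keep) {
  if (is.character(keep)) keep <- match(keep, feature_ids(x))
  x$values <- x$values[, keep, drop = FALSE]
  x$known <- x$known[keep]
  if (!is.null(x$pool_reference)) x$pool_reference <- x$pool_reference[keep]
  x
}
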