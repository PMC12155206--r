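#' Exclude participants by head motion
#'
#' Keeps participants whose mean framewise displacement is *strictly below*
#' the threshold (the inclusion rule "mean FD < 0.7 mm"; a stricter
#' sensitivity threshold of 0.5 mm is common). Rows with missing `mean_fd`
#' are rejected with a warning rather than silently kept.
#'
#' @param cohort participant tibble with a `mean_fd` column (mm).
#' @param threshold exclusion threshold in mm (default 0.7).
#' @return the filtered tibble, row order preserved; excluded participant
#'   ids in attribute `"excluded_ids"`.
#' @export
filter_by_motion <- function(cohort, threshold = 0.7) {
  stopifnot("mean_fd" %in% names(cohort))
  fd <- cohort$mean_fd
  if (anyNA(fd)) {
    warn(sprintf("%d participants with missing mean_fd excluded.", sum(is.na(fd))))
  }
  keep <- !is.na(fd) & fd < threshold
  dropped <- cohort$participant_id[!keep]
  if (length(dropped)) {
    inform(sprintf("motion filter (FD < %g): excluded %d participant(s).",
                   threshold, length(dropped)))
  }
  out <- cohort[keep, , drop = FALSE]
  attr(out, "excluded_ids") <- dropped
  out
}

#' Exclude participants by surface reconstruction quality
#'
#' Excludes participants whose total surface-hole count exceeds `max_holes`
#' (exclusion rule "holes > 380"; counts equal to the bound are kept).
#'
#' @param cohort participant tibble with a `surface_holes` column.
#' @param max_holes maximum acceptable hole count (default 380).
#' @return filtered tibble with attribute `"excluded_ids"`.
#' @export
filter_by_surface_holes <- function(cohort, max_holes = 380) {
  stopifnot("surface_holes" %in% names(cohort))
  holes <- cohort$surface_holes
  if (any(holes < 0, na.rm = TRUE)) abort("negative surface-hole counts.")
  keep <- !is.na(holes) & holes <= max_holes
  dropped <- cohort$participant_id[!keep]
  if (length(dropped)) {
    inform(sprintf("surface-hole filter (> %d excluded): %d participant(s).",
                   max_holes, length(dropped)))
  }
  out <- cohort[keep, , drop = FALSE]
  attr(out, "excluded_ids") <- dropped
  out
}

#' Drop unusable white-matter tracts and impute the remainder
#'
#' Excludes tract features whose unusable-data fraction exceeds
#' `max_unusable` (strictly more than 3% by default; a tract at exactly 3%
#' is retained), then mean-imputes any remaining missing cells per tract.
#'
#' @param features tract feature tibble/matrix (participants x tracts),
#'   optionally with a `participant_id` column.
#' @param max_unusable exclusion threshold on the unusable fraction
#'   (default 0.03).
#' @param unusable_frac optional named per-tract unusable fractions; when
#'   omitted, computed as each tract's missing-cell fraction.
#' @return feature tibble with offending tracts dropped and missing values
#'   imputed; dropped tract names in attribute `"dropped_features"`.
#' @export
filter_tracts <- function(features, max_unusable = 0.03, unusable_frac = NULL) {
  has_id <- is.data.frame(features) && "participant_id" %in% names(features)
  ids <- if (has_id) features$participant_id
  x <- as_feature_matrix(features)
  if (is.null(unusable_frac)) {
    unusable_frac <- colMeans(is.na(x))
  } else {
    if (is.null(names(unusable_frac)) || !all(colnames(x) %in% names(unusable_frac))) {
      abort("unusable_frac must be named for every tract.")
    }
    unusable_frac <- unusable_frac[colnames(x)]
  }
  drop <- unusable_frac > max_unusable
  if (all(drop)) abort("all tracts exceed the unusable-data threshold.")
  if (any(drop)) {
    inform(sprintf("tract filter (> %g%% unusable): dropped %s",
                   100 * max_unusable,
                   paste(colnames(x)[drop], collapse = ", ")))
  }
  x <- x[, !drop, drop = FALSE]
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) {
      if (all(miss)) abort(sprintf("tract %s is fully missing.", colnames(x)[j]))
      x[miss, j] <- mean(x[!miss, j])
    }
  }
  out <- tibble::as_tibble(x)
  if (has_id) out <- dplyr::bind_cols(tibble::tibble(participant_id = ids), out)
  attr(out, "dropped_features") <- names(unusable_frac)[drop]
  out
}

#' Mean-impute missing cognitive scores
#'
#' Replaces each missing test score with the observed-sample mean of that
#' test, so multivariate analyses can run on the full sample. Observed cells
#' are untouched; the missingness mask is retained for audit in attribute
#' `"missing_mask"`.
#'
#' @param cognition participants x tests tibble (optionally with
#'   `participant_id`).
#' @return imputed tibble with the audit mask attached.
#' @export
impute_cognition_mean <- function(cognition) {
  has_id <- is.data.frame(cognition) && "participant_id" %in% names(cognition)
  ids <- if (has_id) cognition$participant_id
  x <- as_feature_matrix(cognition)
  mask <- is.na(x)
  full <- colSums(!mask) == 0
  if (any(full)) {
    abort(sprintf("test(s) fully missing, cannot impute: %s",
                  paste(colnames(x)[full], collapse = ", ")))
  }
  for (j in which(colSums(mask) > 0)) {
    x[mask[, j], j] <- mean(x[!mask[, j], j])
  }
  out <- tibble::as_tibble(x)
  if (has_id) out <- dplyr::bind_cols(tibble::tibble(participant_id = ids), out)
  attr(out, "missing_mask") <- mask
  out
}

#' White-matter hyperintensity burden, ICV-corrected and square-root
#' transformed
#'
#' `sqrt(wmh_volume / icv)`: lesion volume as a fraction of total
#' intracranial volume, square-root transformed to de-skew.
#'
#' @param wmh_volume lesion volume (mm^3), >= 0.
#' @param icv total intracranial volume (mm^3), > 0.
#' @return transformed score, same length as the inputs.
#' @export
transform_wmh <- function(wmh_volume, icv) {
  if (any(is.na(wmh_volume)) || any(is.na(icv))) abort("missing volumes.")
  if (any(wmh_volume < 0)) abort("wmh_volume must be non-negative.")
  if (any(icv <= 0)) abort("icv must be positive.")
  sqrt(wmh_volume / icv)
}

#' Column-wise z-scoring with recoverable parameters
#'
#' Standardizes every column to mean 0 and SD 1 (n-1 denominator), returning
#' the fitted means and SDs so held-out data can be standardized with
#' training-set parameters (no test-set leakage). A zero-variance column is
#' an error naming the column.
#'
#' @param data numeric tibble/matrix (optionally with `participant_id`); no
#'   missing cells; at least 2 rows.
#' @return standardized tibble with attribute `"scaler"` (list with
#'   `center`, `scale`).
#' @seealso [apply_zscore()], [invert_zscore()]
#' @export
zscore_columns <- function(data) {
  has_id <- is.data.frame(data) && "participant_id" %in% names(data)
  ids <- if (has_id) data$participant_id
  x <- as_feature_matrix(data)
  if (nrow(x) < 2) abort("need at least 2 rows to standardize.")
  if (anyNA(x)) abort("missing cells; impute before standardizing.")
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  zero <- scl <= 0 | !is.finite(scl)
  if (any(zero)) {
    abort(sprintf("zero-variance column(s): %s",
                  paste(colnames(x)[zero], collapse = ", ")))
  }
  z <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
  out <- tibble::as_tibble(z)
  if (has_id) out <- dplyr::bind_cols(tibble::tibble(participant_id = ids), out)
  attr(out, "scaler") <- list(center = ctr, scale = scl)
  out
}

#' Extract the scaler fitted by [zscore_columns()]
#' @param data output of [zscore_columns()].
#' @return list with `center` and `scale`.
#' @export
zscore_params <- function(data) {
  sc <- attr(data, "scaler")
  if (is.null(sc)) abort("no scaler attached; standardize with zscore_columns().")
  sc
}

#' Standardize new data with a previously fitted scaler
#' @param data numeric tibble/matrix with the same columns the scaler was
#'   fitted on.
#' @param scaler list with `center` and `scale` (from [zscore_params()]).
#' @return standardized tibble.
#' @export
apply_zscore <- function(data, scaler) {
  has_id <- is.data.frame(data) && "participant_id" %in% names(data)
  ids <- if (has_id) data$participant_id
  x <- as_feature_matrix(data)
  if (!all(names(scaler$center) %in% colnames(x))) {
    abort("scaler columns missing from data.")
  }
  x <- x[, names(scaler$center), drop = FALSE]
  z <- sweep(sweep(x, 2, scaler$center, "-"), 2, scaler$scale, "/")
  out <- tibble::as_tibble(z)
  if (has_id) out <- dplyr::bind_cols(tibble::tibble(participant_id = ids), out)
  attr(out, "scaler") <- scaler
  out
}

#' Undo standardization with a fitted scaler
#' @inheritParams apply_zscore
#' @return tibble on the original scale.
#' @export
invert_zscore <- function(data, scaler) {
  has_id <- is.data.frame(data) && "participant_id" %in% names(data)
  ids <- if (has_id) data$participant_id
  x <- as_feature_matrix(data)
  x <- x[, names(scaler$center), drop = FALSE]
  raw <- sweep(sweep(x, 2, scaler$scale, "*"), 2, scaler$center, "+")
  out <- tibble::as_tibble(raw)
  if (has_id) out <- dplyr::bind_cols(tibble::tibble(participant_id = ids), out)
  out
}
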