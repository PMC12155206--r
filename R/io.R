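#' Read a participant (cohort) table
#'
#' Comma-separated, header row, `participant_id` first column. The schema is
#' validated: required columns must be present, `participant_id` unique,
#' `mean_fd` non-negative and `icv` positive.
#'
#' @param path CSV file.
#' @return a tibble.
#' @export
read_cohort_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("participant_id", "site", "age", "sex", "mean_fd", "icv")
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    abort(sprintf("cohort table %s is missing column(s): %s",
                  path, paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(x$participant_id)) {
    abort("participant_id values are not unique.")
  }
  if (any(x$mean_fd < 0, na.rm = TRUE)) abort("mean_fd must be >= 0.")
  if (any(x$icv <= 0, na.rm = TRUE)) abort("icv must be > 0.")
  x
}

#' Read a cognition table
#' @param path CSV with `participant_id` plus one column per test.
#' @return a tibble.
#' @export
read_cognition_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!"participant_id" %in% names(x)) {
    abort("cognition table must have a participant_id column.")
  }
  if (ncol(x) < 2) abort("cognition table has no test columns.")
  x
}

#' Read a brain feature table
#' @param path CSV with `participant_id` plus one column per feature.
#' @param modality optional tag (`"FC"`, `"WM"`, `"GM"`) stored as an
#'   attribute.
#' @return a tibble.
#' @export
read_feature_table <- function(path, modality = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!"participant_id" %in% names(x)) {
    abort("feature table must have a participant_id column.")
  }
  num <- vapply(x[-1], is.numeric, logical(1))
  if (!all(num)) {
    abort(sprintf("non-numeric feature column(s) in %s: %s", path,
                  paste(names(x[-1])[!num], collapse = ", ")))
  }
  if (!is.null(modality)) attr(x, "modality") <- modality
  x
}

# Ingest a directory written by write_cohort(): cohort.csv, cognition.csv,
# features_<modality>.csv. Returns the same shape as generate_cohort()
# (without ground truth).
read_cohort_dir <- function(dir) {
  cohort <- read_cohort_table(file.path(dir, "cohort.csv"))
  cognition <- read_cognition_table(file.path(dir, "cognition.csv"))
  feat_files <- list.files(dir, pattern = "^features_.*\\.csv$",
                           full.names = TRUE)
  if (!length(feat_files)) abort(sprintf("no features_*.csv in %s", dir))
  features <- list()
  for (f in feat_files) {
    mod <- toupper(sub("^features_(.*)\\.csv$", "\\1", basename(f)))
    features[[mod]] <- read_feature_table(f, modality = mod)
  }
  ids <- cohort$participant_id
  for (nm in names(features)) {
    if (!identical(features[[nm]]$participant_id, ids)) {
      abort(sprintf("feature table %s is not aligned with the cohort.", nm))
    }
  }
  structure(list(cohort = cohort, cognition = cognition, features = features,
                 truth = NULL, config = NULL), class = "lc_cohort_sim")
}
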