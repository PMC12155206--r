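#' Configuration for the end-to-end pipeline
#'
#' Bundles every stage's settings: data source (synthetic generator or a
#' directory of delimited-text tables), QC thresholds, harmonization
#' covariates, per-modality PLS resampling sizes, leave-one-site-out and
#' prediction settings, and a single master seed from which each stage's
#' seed is derived deterministically (a stage-label hash of the master seed).
#'
#' @param generator a [generator_config()] (synthetic mode), or `NULL` when
#'   reading from `input_dir`.
#' @param input_dir directory with `cohort.csv`, `cognition.csv` and
#'   `features_<modality>.csv` tables (ingest mode).
#' @param fd_threshold motion exclusion threshold, mm (default 0.7).
#' @param max_holes surface-hole exclusion bound (default 380).
#' @param max_unusable tract unusable-data bound (default 0.03).
#' @param harmonize_gm harmonize gray-matter features too (default `FALSE`:
#'   only functional connectivity and diffusion features are adjusted).
#' @param n_perm,n_boot resampling sizes for model significance and loading
#'   robustness (study-scale defaults 5000).
#' @param z_threshold bootstrap-ratio robustness threshold (default 3).
#' @param max_components cap for the sequential component rule.
#' @param loso run leave-one-site-out generalizability (default `TRUE`).
#' @param loso_n_perm permutations inside each LOSO training fold.
#' @param n_iter,test_n,inner_folds,stability_threshold prediction settings
#'   (defaults 100, 20, 10, 0.95).
#' @param eval_folds folds for the parsimonious-model evaluation (default 8).
#' @param seed master seed.
#' @param output_dir where tables, the manifest and the report are written.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            input_dir = NULL,
                            fd_threshold = 0.7, max_holes = 380,
                            max_unusable = 0.03, harmonize_gm = FALSE,
                            n_perm = 5000, n_boot = 5000, z_threshold = 3,
                            max_components = 3, loso = TRUE, loso_n_perm = 200,
                            n_iter = 100, test_n = 20, inner_folds = 10,
                            stability_threshold = 0.95, eval_folds = 8,
                            seed = 1L, output_dir = tempfile("latentcog_run_")) {
  if (is.null(generator) && is.null(input_dir)) {
    abort("provide a generator config or an input directory.")
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    abort(sprintf("input_dir does not exist: %s", input_dir))
  }
  stopifnot(fd_threshold > 0, max_holes >= 0, max_unusable >= 0,
            n_perm >= 1, n_boot >= 1, z_threshold > 0, n_iter >= 1)
  structure(list(
    generator = generator, input_dir = input_dir,
    fd_threshold = fd_threshold, max_holes = max_holes,
    max_unusable = max_unusable, harmonize_gm = harmonize_gm,
    n_perm = n_perm, n_boot = n_boot, z_threshold = z_threshold,
    max_components = max_components, loso = loso, loso_n_perm = loso_n_perm,
    n_iter = n_iter, test_n = test_n, inner_folds = inner_folds,
    stability_threshold = stability_threshold, eval_folds = eval_folds,
    seed = as.integer(seed), output_dir = output_dir
  ), class = "pipeline_config")
}

#' Run the full brain-cognition pipeline
#'
#' Executes, in order: data generation (or ingestion) -> QC filters and
#' imputation -> site harmonization -> per-modality PLS with permutation and
#' bootstrap inference and latent-test correlations -> follow-up covariate
#' associations -> leave-one-site-out generalizability -> remission
#' prediction (nested elastic net + stability selection + parsimonious
#' evaluation) and the continuous symptom-change PLS. Every intermediate
#' table is written as delimited text, with a JSON run manifest and a plain
#' text summary report. Identical config + seed reproduce every output
#' byte-for-byte.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a named list with every stage result.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) inform(sprintf(...))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  # ---- stage 1: data -------------------------------------------------
  say("[1/6] data")
  if (!is.null(config$input_dir)) {
    sim <- read_cohort_dir(config$input_dir)
  } else {
    gcfg <- config$generator
    gcfg$seed <- derive_seed(seed, "generate")
    sim <- generate_cohort(gcfg)
  }
  cohort <- sim$cohort

  # ---- stage 2: QC / prep -------------------------------------------
  say("[2/6] QC filters, imputation, transforms")
  cohort <- filter_by_motion(cohort, config$fd_threshold)
  cohort <- filter_by_surface_holes(cohort, config$max_holes)
  keep <- cohort$participant_id
  cognition <- dplyr::filter(sim$cognition, .data$participant_id %in% keep)
  features <- lapply(sim$features, function(f) {
    dplyr::filter(f, .data$participant_id %in% keep)
  })
  if ("WM" %in% names(features)) {
    features$WM <- filter_tracts(features$WM, config$max_unusable)
  }
  cognition <- impute_cognition_mean(cognition)
  cohort$wmh_score <- transform_wmh(cohort$wmh_volume, cohort$icv)

  # ---- stage 3: harmonization ---------------------------------------
  say("[3/6] site harmonization")
  harm_models <- list()
  harm_covs <- list(FC = c("age", "sex", "mean_fd"), WM = c("age", "sex"),
                    GM = c("age", "sex"))
  for (mod in names(features)) {
    if (mod == "GM" && !config$harmonize_gm) next
    m <- fit_harmonization(features[[mod]], cohort,
                           covariates = harm_covs[[mod]] %||% c("age", "sex"))
    features[[mod]] <- apply_harmonization(m, features[[mod]], cohort)
    harm_models[[mod]] <- m
  }

  # ---- stage 4: PLS per modality ------------------------------------
  say("[4/6] PLS models (permutation + bootstrap)")
  Yz <- zscore_columns(cognition)
  pls_results <- list()
  for (mod in names(features)) {
    Xz <- zscore_columns(features[[mod]])
    k_sel <- select_n_components(
      Xz, Yz, max_components = config$max_components,
      n_perm = min(config$n_perm, 500),
      seed = derive_seed(seed, paste0("ncomp_", mod)))
    k_fit <- max(k_sel, 1L)
    fit <- fit_pls(Xz, Yz, n_components = k_fit, check = FALSE)
    perm <- permutation_test(Xz, Yz, n_components = k_fit,
                             n_perm = config$n_perm,
                             seed = derive_seed(seed, paste0("perm_", mod)))
    boot <- bootstrap_loadings(Xz, Yz, n_components = k_fit,
                               n_boot = config$n_boot,
                               z_threshold = config$z_threshold,
                               seed = derive_seed(seed, paste0("boot_", mod)))
    ltc <- latent_test_correlations(fit, Yz)
    assoc <- dplyr::bind_rows(lapply(
      c("education", "centile", "athf", "wmh_score"),
      function(v) {
        dplyr::mutate(
          association_with_covariate(fit$x_scores[, 1L], cohort[[v]]),
          covariate = v, .before = 1)
      }))
    pls_results[[mod]] <- list(
      n_components_selected = k_sel, fit = fit, permutation = perm,
      bootstrap = boot, latent_test = ltc, covariate_associations = assoc,
      significant = k_sel >= 1L && perm$p_value < 0.05)
  }

  # ---- stage 5: generalizability ------------------------------------
  loso_results <- list()
  if (config$loso) {
    say("[5/6] leave-one-site-out generalizability")
    for (mod in names(features)) {
      k <- max(pls_results[[mod]]$n_components_selected, 1L)
      loso_results[[mod]] <- leave_one_site_out(
        features[[mod]], cognition, cohort$site, n_components = k,
        n_perm = config$loso_n_perm,
        seed = derive_seed(seed, paste0("loso_", mod)))
    }
  } else {
    say("[5/6] leave-one-site-out skipped")
  }

  # ---- stage 6: outcome prediction ----------------------------------
  say("[6/6] remission prediction + symptom-change PLS")
  pred_features <- dplyr::bind_cols(
    dplyr::select(cohort, "age", "sex", "education", "madrs_baseline",
                  "athf", "cirs_g", "wmh_score", "centile"),
    dplyr::select(cognition, -"participant_id"),
    dplyr::select(features$GM, -"participant_id"))
  run <- nested_elasticnet(pred_features, cohort$remission,
                           n_iter = config$n_iter, test_n = config$test_n,
                           inner_folds = config$inner_folds,
                           seed = derive_seed(seed, "elasticnet"))
  parsimonious <- suppressWarnings(
    stability_select(run, config$stability_threshold))
  parsimonious_used <- parsimonious
  if (!length(parsimonious_used)) {
    say("  no stable features; evaluating the top 3 by frequency instead")
    parsimonious_used <- head(run$stability$feature, 3)
  }
  eval_pars <- evaluate_parsimonious(
    pred_features[, parsimonious_used, drop = FALSE], cohort$remission,
    k_folds = config$eval_folds, seed = derive_seed(seed, "eval"))
  change <- pls_madrs_change(pred_features, cohort$madrs_change,
                             n_components = 1,
                             n_perm = min(config$n_perm, 1000),
                             seed = derive_seed(seed, "change"))

  results <- list(cohort = cohort, cognition = cognition,
                  features = features, harmonization = harm_models,
                  pls = pls_results, loso = loso_results,
                  prediction = list(run = run, parsimonious = parsimonious,
                                    parsimonious_used = parsimonious_used,
                                    evaluation = eval_pars, change = change),
                  config = config)
  write_pipeline_outputs(results, out_dir)
  say("done: %s", out_dir)
  invisible(results)
}

write_pipeline_outputs <- function(results, out_dir) {
  w <- function(x, f) readr::write_csv(x, file.path(out_dir, f))
  w(results$cohort, "cohort_prepped.csv")
  w(results$cognition, "cognition_imputed.csv")
  for (mod in names(results$features)) {
    w(results$features[[mod]], sprintf("features_%s_harmonized.csv", tolower(mod)))
  }
  pls_summary <- dplyr::bind_rows(lapply(names(results$pls), function(mod) {
    r <- results$pls[[mod]]
    tibble::tibble(
      modality = mod,
      n_components_selected = r$n_components_selected,
      variance_explained = r$fit$total_variance_explained,
      permutation_p = r$permutation$p_value,
      significant = r$significant,
      n_robust_features = sum(rowSums(r$bootstrap$significant_mask) > 0))
  }))
  w(pls_summary, "pls_summary.csv")
  for (mod in names(results$pls)) {
    w(tidy(results$pls[[mod]]$bootstrap),
      sprintf("bootstrap_z_%s.csv", tolower(mod)))
    w(results$pls[[mod]]$latent_test,
      sprintf("latent_test_correlations_%s.csv", tolower(mod)))
    w(results$pls[[mod]]$covariate_associations,
      sprintf("covariate_associations_%s.csv", tolower(mod)))
  }
  if (length(results$loso)) {
    loso_tbl <- dplyr::bind_rows(lapply(names(results$loso), function(mod) {
      dplyr::mutate(results$loso[[mod]]$by_site, modality = mod, .before = 1)
    }))
    w(loso_tbl, "loso_results.csv")
  }
  pred <- results$prediction
  w(dplyr::select(pred$run$iterations, -"selected", -"test_ids"),
    "prediction_iterations.csv")
  w(pred$run$stability, "stability_frequencies.csv")
  w(pred$evaluation$confusion, "confusion_matrix.csv")

  manifest <- list(
    package = "latentcog",
    version = as.character(utils::packageVersion("latentcog")),
    seed = results$config$seed,
    config = unclass(results$config)[setdiff(names(unclass(results$config)),
                                             c("generator", "output_dir"))],
    generator = if (!is.null(results$config$generator)) {
      unclass(results$config$generator)
    },
    n_participants_analyzed = nrow(results$cohort)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(render_report(results, pls_summary), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

render_report <- function(results, pls_summary) {
  pred <- results$prediction
  c(
    "latentcog pipeline report",
    strrep("=", 60),
    "",
    "[1] Sample",
    sprintf("  participants after QC: %d (sites: %s)", nrow(results$cohort),
            paste(sort(unique(results$cohort$site)), collapse = ", ")),
    sprintf("  remission rate: %.2f", mean(results$cohort$remission)),
    "",
    "[2] Harmonization",
    if (length(results$harmonization)) {
      vapply(names(results$harmonization), function(mod) {
        m <- results$harmonization[[mod]]
        sprintf("  %s: %d features, covariates protected: %s", mod,
                length(m$feature_names), paste(m$covariates, collapse = ", "))
      }, character(1))
    } else "  (no modality harmonized)",
    "",
    "[3] PLS brain-cognition models",
    apply(pls_summary, 1, function(r) {
      sprintf("  %s: %s components, varexp = %.1f%%, permutation p = %s (%s)",
              r[["modality"]], r[["n_components_selected"]],
              100 * as.numeric(r[["variance_explained"]]),
              format(as.numeric(r[["permutation_p"]]), digits = 3),
              if (as.logical(r[["significant"]])) "significant" else "not significant")
    }),
    "",
    "[4] Generalizability (leave-one-site-out)",
    if (length(results$loso)) {
      vapply(names(results$loso), function(mod) {
        sprintf("  %s: mean held-out r = %.3f",
                mod, mean(results$loso[[mod]]$by_site$r, na.rm = TRUE))
      }, character(1))
    } else "  (skipped)",
    "",
    "[5] Outcome prediction",
    sprintf("  nested elastic net: mean held-out AUC = %.3f [%.3f, %.3f]",
            pred$run$mean_auc, pred$run$auc_interval[1], pred$run$auc_interval[2]),
    sprintf("  stable features (> %.0f%%): %s",
            100 * results$config$stability_threshold,
            if (length(pred$parsimonious)) paste(pred$parsimonious, collapse = ", ")
            else "(none)"),
    sprintf("  parsimonious model (%d-fold): AUC = %.3f, sens = %.2f, spec = %.2f",
            pred$evaluation$k_folds, pred$evaluation$auc,
            pred$evaluation$confusion$sensitivity,
            pred$evaluation$confusion$specificity),
    sprintf("  symptom-change PLS: varexp = %.1f%%, permutation p = %s, holdout r = %.3f",
            100 * pred$change$variance_explained,
            format(pred$change$permutation$p_value, digits = 3),
            pred$change$holdout_r)
  )
}
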