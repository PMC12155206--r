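#' Configuration for the multi-site synthetic cohort generator
#'
#' Defines the study conditions a simulated cohort emulates: a multi-site
#' late-life treatment-resistant depression sample with three brain feature
#' modalities (functional connectivity edges, white-matter tract FA,
#' gray-matter structure), a 12-test cognitive battery spanning six domains,
#' a small number of shared latent factors linking brain features to
#' cognition, additive/multiplicative site batch effects, covariate effects
#' of age, sex and head motion, and a logistic remission outcome driven by a
#' sparse feature subset.
#'
#' @param n_participants cohort size (default 230, the scale of a multi-site
#'   imaging subsample).
#' @param n_sites number of acquisition sites (default 4).
#' @param features_per_modality named counts of brain features; defaults
#'   `c(FC = 210, WM = 62, GM = 74)` (210 = 21*20/2 pairwise connectivities).
#' @param n_cognitive_tests number of cognitive tests (default 12).
#' @param n_latent_factors number of shared brain-cognition factors.
#' @param loading_sparsity fraction of each modality's features carrying each
#'   factor.
#' @param signal_strength fraction of cognition variance explained by the
#'   latent factors, in \[0, 1); 0 plants a pure null.
#' @param factor_feature_cor population correlation between a loaded brain
#'   feature and its factor (default 0.5).
#' @param site_location_sd SD of additive per-site, per-feature shifts.
#' @param site_scale_sd SD (log scale) of multiplicative per-site,
#'   per-feature scale factors.
#' @param covariate_effects named slopes (per SD of covariate, in feature SD
#'   units) for `age`, `sex` and `motion` effects on brain features.
#' @param outcome_n_informative number of gray-matter features driving
#'   remission.
#' @param outcome_auc_target discrimination of the true linear predictor
#'   (AUC, 0.5 = null).
#' @param outcome_prevalence target remission rate (default 0.45).
#' @param change_r2 fraction of variance in continuous symptom change
#'   explained by the informative features (default 0.3).
#' @param missing_cognition_rate MCAR missingness rate for cognitive scores
#'   (default 0.04, i.e. the low per-test missingness regime where mean
#'   imputation is defensible).
#' @param seed integer; fully determines generator output.
#' @return a validated `lc_generator_config` list.
#' @export
generator_config <- function(n_participants = 230,
                             n_sites = 4,
                             features_per_modality = c(FC = 210, WM = 62, GM = 74),
                             n_cognitive_tests = 12,
                             n_latent_factors = 2,
                             loading_sparsity = 0.2,
                             signal_strength = 0.10,
                             factor_feature_cor = 0.5,
                             site_location_sd = 0.4,
                             site_scale_sd = 0.2,
                             covariate_effects = c(age = -0.15, sex = 0.1, motion = -0.1),
                             outcome_n_informative = 5,
                             outcome_auc_target = 0.75,
                             outcome_prevalence = 0.45,
                             change_r2 = 0.3,
                             missing_cognition_rate = 0.04,
                             seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_sites = as.integer(n_sites),
    features_per_modality = features_per_modality,
    n_cognitive_tests = as.integer(n_cognitive_tests),
    n_latent_factors = as.integer(n_latent_factors),
    loading_sparsity = loading_sparsity,
    signal_strength = signal_strength,
    factor_feature_cor = factor_feature_cor,
    site_location_sd = site_location_sd,
    site_scale_sd = site_scale_sd,
    covariate_effects = covariate_effects,
    outcome_n_informative = as.integer(outcome_n_informative),
    outcome_auc_target = outcome_auc_target,
    outcome_prevalence = outcome_prevalence,
    change_r2 = change_r2,
    missing_cognition_rate = missing_cognition_rate,
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "lc_generator_config")
}

validate_generator_config <- function(cfg) {
  counts <- c(cfg$n_participants, cfg$n_sites, cfg$n_cognitive_tests,
              cfg$features_per_modality)
  if (any(counts <= 0)) abort("all counts must be positive.")
  if (cfg$n_latent_factors < 0) abort("n_latent_factors must be >= 0.")
  if (cfg$signal_strength < 0 || cfg$signal_strength >= 1) {
    abort("signal_strength must lie in [0, 1).")
  }
  if (cfg$missing_cognition_rate < 0 || cfg$missing_cognition_rate > 0.2) {
    abort("missing_cognition_rate must lie in [0, 0.2].")
  }
  if (is.null(names(cfg$features_per_modality)) ||
      any(!nzchar(names(cfg$features_per_modality)))) {
    abort("features_per_modality must be a named vector.")
  }
  if (cfg$outcome_auc_target < 0.5 || cfg$outcome_auc_target >= 1) {
    abort("outcome_auc_target must lie in [0.5, 1).")
  }
  if (cfg$outcome_n_informative > cfg$features_per_modality[["GM"]] %||% Inf) {
    abort("outcome_n_informative exceeds the GM feature count.")
  }
  if (cfg$change_r2 < 0 || cfg$change_r2 >= 1) abort("change_r2 must lie in [0, 1).")
  invisible(cfg)
}

#' Cognitive domain labels for the 12-test battery
#'
#' Two tests per domain across attention, immediate memory, delayed memory,
#' language, visuospatial and executive function.
#' @return a tibble with `test` and `domain` columns.
#' @export
cognitive_domains <- function() {
  tibble::tibble(
    test = sprintf("test%02d", 1:12),
    domain = rep(c("attention", "immediate_memory", "delayed_memory",
                   "language", "visuospatial", "executive"), each = 2)
  )
}

#' Generate a multi-site synthetic cohort with known latent ground truth
#'
#' Simulates a cohort under the latent-factor model
#' \eqn{Y = F L_y' + E_y}, \eqn{X = F L_x' + E_x} with shared factor scores
#' F: each factor loads on a sparse subset of brain features in every
#' modality and on a disjoint block of cognitive tests, with noise variances
#' solved analytically so the factors explain exactly `signal_strength` of
#' cognition variance in the population. Site batch effects
#' (additive location, multiplicative scale), covariate effects (age, sex,
#' motion) and MCAR cognitive missingness are then layered on, and remission
#' labels are drawn from a logistic model on a sparse gray-matter subset
#' calibrated to `outcome_auc_target`.
#'
#' @param config a [generator_config()].
#' @return a list of class `lc_cohort_sim`:
#' \describe{
#'   \item{cohort}{participant-level tibble (site, demographics, clinical
#'     scores, QC metrics, remission, MADRS change).}
#'   \item{cognition}{participants x 12 test-score tibble (with NAs at the
#'     configured MCAR rate).}
#'   \item{features}{named list of participants x features tibbles, one per
#'     modality, `participant_id` first column.}
#'   \item{truth}{ground-truth object: factor scores and loadings, planted
#'     variance explained, per-site location/scale effects, informative
#'     feature ids and outcome coefficients.}
#' }
#' @examples
#' sim <- generate_cohort(generator_config(n_participants = 60, seed = 7))
#' dim(sim$cognition)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "lc_generator_config"))
  validate_generator_config(config)
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_participants
  K <- cfg$n_latent_factors
  q <- cfg$n_cognitive_tests
  ids <- sprintf("P%04d", seq_len(n))
  sites <- sample(rep_len(sprintf("site%02d", seq_len(cfg$n_sites)), n))

  # demographics / clinical / QC marginals typical of a late-life
  # treatment-resistant depression trial sample
  age <- rnorm(n, 68, 6)
  sex <- rbinom(n, 1, 0.68)
  education <- pmax(8, round(rnorm(n, 15, 2.5)))
  mean_fd <- rlnorm(n, log(0.25), 0.45)
  icv <- rnorm(n, 1.45e6, 1.4e5)
  wmh_volume <- rgamma(n, shape = 2, scale = 1800)
  surface_holes <- rnbinom(n, mu = 120, size = 2)
  madrs_baseline <- pmin(45, pmax(20, round(rnorm(n, 28, 5))))
  athf <- sample(1:8, n, replace = TRUE)
  cirs_g <- rpois(n, 9)
  centile <- rbeta(n, 2, 2)

  # shared latent factors; pure null when signal_strength = 0 (factors still
  # drawn, but carry no loading weight)
  f_scores <- matrix(rnorm(n * max(K, 1L)), n, max(K, 1L))
  s <- cfg$signal_strength

  # cognition: factors partition the battery into disjoint blocks, each test
  # explained exactly s by its factor
  ly <- matrix(0, q, max(K, 1L))
  if (K > 0 && s > 0) {
    block <- rep_len(seq_len(K), q)
    for (k in seq_len(K)) ly[block == k, k] <- sqrt(s)
  }
  ey_sd <- sqrt(1 - rowSums(ly^2))
  y_clean <- f_scores %*% t(ly) + matrix(rnorm(n * q), n, q) * rep(ey_sd, each = n)
  colnames(y_clean) <- sprintf("test%02d", seq_len(q))

  covars <- cbind(age = as.numeric(scale(age)),
                  sex = sex - mean(sex),
                  motion = as.numeric(scale(mean_fd)))
  slopes <- cfg$covariate_effects[c("age", "sex", "motion")]
  slopes[is.na(slopes)] <- 0

  lx <- list(); site_loc <- list(); site_scl <- list(); feats <- list()
  for (mod in names(cfg$features_per_modality)) {
    p <- cfg$features_per_modality[[mod]]
    L <- matrix(0, p, max(K, 1L))
    if (K > 0 && s > 0) {
      n_load <- max(1L, round(cfg$loading_sparsity * p))
      for (k in seq_len(K)) {
        L[sample.int(p, n_load), k] <- cfg$factor_feature_cor
      }
    }
    noise_sd <- sqrt(pmax(1 - rowSums(L^2), 0.05))
    base <- f_scores %*% t(L) + matrix(rnorm(n * p), n, p) * rep(noise_sd, each = n)
    gl <- matrix(rnorm(cfg$n_sites * p, 0, cfg$site_location_sd), cfg$n_sites, p)
    gs <- matrix(exp(rnorm(cfg$n_sites * p, 0, cfg$site_scale_sd)), cfg$n_sites, p)
    site_idx <- as.integer(factor(sites, levels = sprintf("site%02d", seq_len(cfg$n_sites))))
    out <- gl[site_idx, , drop = FALSE] + gs[site_idx, , drop = FALSE] * base +
      covars %*% matrix(slopes, 3, p)
    fnames <- switch(mod,
      FC = fc_edge_names(p),
      sprintf("%s_%03d", tolower(mod), seq_len(p)))
    colnames(out) <- fnames
    rownames(gl) <- rownames(gs) <- sprintf("site%02d", seq_len(cfg$n_sites))
    colnames(gl) <- colnames(gs) <- fnames
    colnames(L) <- sprintf("factor%d", seq_len(ncol(L)))
    rownames(L) <- fnames
    lx[[mod]] <- L
    site_loc[[mod]] <- gl
    site_scl[[mod]] <- gs
    feats[[mod]] <- tibble::as_tibble(cbind(
      tibble::tibble(participant_id = ids), tibble::as_tibble(out)))
  }

  # MCAR deletion of cognitive scores
  y_obs <- y_clean
  if (cfg$missing_cognition_rate > 0) {
    miss <- matrix(runif(n * q) < cfg$missing_cognition_rate, n, q)
    y_obs[miss] <- NA_real_
  }

  # remission labels from a logistic model on informative GM features
  gm <- as_feature_matrix(feats$GM)
  inf_ids <- sample(colnames(gm), cfg$outcome_n_informative)
  beta_sign <- sample(c(-1, 1), cfg$outcome_n_informative, replace = TRUE)
  eta_raw <- as.numeric(gm[, inf_ids, drop = FALSE] %*% beta_sign)
  eta_z <- if (sd(eta_raw) > 0) as.numeric(scale(eta_raw)) else eta_raw
  lab <- draw_outcome_labels(eta_z, cfg$outcome_auc_target, cfg$outcome_prevalence)

  # continuous symptom change driven by the same informative features
  r2 <- cfg$change_r2
  change_lin <- sqrt(r2) * eta_z + sqrt(1 - r2) * rnorm(n)
  madrs_change <- round(-10 - 7 * change_lin) # negative = improvement

  cohort <- tibble::tibble(
    participant_id = ids, site = sites, age = age, sex = sex,
    education = education, madrs_baseline = madrs_baseline,
    madrs_change = madrs_change, remission = lab$labels, athf = athf,
    cirs_g = cirs_g, mean_fd = mean_fd, icv = icv,
    wmh_volume = wmh_volume, centile = centile,
    surface_holes = surface_holes)

  truth <- structure(list(
    factor_scores = f_scores,
    factor_loadings_X = lx,
    factor_loadings_Y = ly,
    planted_variance_explained = s,
    site_location = site_loc,
    site_scale = site_scl,
    informative_feature_ids = inf_ids,
    outcome_coefficients = setNames(lab$slope * beta_sign / max(sd(eta_raw), 1e-12), inf_ids),
    outcome_intercept = lab$intercept,
    true_linear_predictor = lab$slope * eta_z + lab$intercept,
    change_linear_predictor = change_lin,
    seed = cfg$seed
  ), class = "lc_synthetic_truth")

  structure(list(
    cohort = cohort,
    cognition = tibble::as_tibble(cbind(tibble::tibble(participant_id = ids),
                                        tibble::as_tibble(y_obs))),
    features = feats,
    truth = truth,
    config = cfg
  ), class = "lc_cohort_sim")
}

fc_edge_names <- function(p) {
  # pairwise edges among k network components, k(k-1)/2 = p when p is
  # triangular; otherwise fall back to sequential edge labels
  k <- (1 + sqrt(1 + 8 * p)) / 2
  if (abs(k - round(k)) < 1e-9) {
    k <- round(k)
    pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
    sprintf("fc_ic%02d_ic%02d", pairs[, 1], pairs[, 2])
  } else {
    sprintf("fc_edge%03d", seq_len(p))
  }
}

# AUC of a Bernoulli-logistic outcome whose linear predictor is N(0, slope^2)
# shifted by `intercept`, by Gauss-type quadrature on a fine grid.
logistic_auc_given_slope <- function(slope, intercept = 0) {
  if (slope <= 0) return(0.5)
  z <- seq(-8, 8, length.out = 4001) * slope
  w <- dnorm(z, 0, slope); w <- w / sum(w)
  p <- plogis(z + intercept)
  pos <- p * w; neg <- (1 - p) * w
  cneg <- cumsum(neg) - neg / 2 # midpoint correction for ties at same node
  sum(pos * cneg) / (sum(pos) * sum(neg))
}

calibrate_outcome_slope <- function(auc_target, intercept = 0) {
  if (auc_target <= 0.5) return(0)
  uniroot(function(b) logistic_auc_given_slope(b, intercept) - auc_target,
          c(1e-6, 50), tol = 1e-8)$root
}

draw_outcome_labels <- function(eta_z, auc_target, prevalence, max_retries = 10L) {
  slope <- calibrate_outcome_slope(auc_target)
  # intercept chosen so the expected label rate hits the target prevalence
  intercept <- uniroot(function(a) mean(plogis(slope * eta_z + a)) - prevalence,
                       c(-20, 20), tol = 1e-8)$root
  eta <- slope * eta_z + intercept
  for (i in seq_len(max_retries)) {
    labels <- rbinom(length(eta), 1, plogis(eta))
    if (length(unique(labels)) > 1L) {
      return(list(labels = labels, slope = slope, intercept = intercept))
    }
    warn("degenerate single-class label draw; regenerating.")
  }
  abort("could not draw a two-class outcome within the retry budget.")
}

#' Draw remission labels from the planted logistic outcome model
#'
#' Re-draws binary outcome labels for a feature matrix using the ground-truth
#' informative features and coefficients, calibrated so the true linear
#' predictor discriminates at `config$outcome_auc_target`.
#'
#' @param features a feature tibble/matrix containing the informative columns.
#' @param truth the `lc_synthetic_truth` from [generate_cohort()].
#' @param config the [generator_config()] used.
#' @param seed optional seed for the label draw.
#' @return integer 0/1 labels.
#' @export
generate_outcome_labels <- function(features, truth, config, seed = NULL) {
  x <- as_feature_matrix(features)
  inf <- truth$informative_feature_ids
  if (!all(inf %in% colnames(x))) {
    abort("informative features missing from the supplied matrix.")
  }
  eta_raw <- as.numeric(x[, inf, drop = FALSE] %*% sign(truth$outcome_coefficients))
  eta_z <- if (sd(eta_raw) > 0) as.numeric(scale(eta_raw)) else eta_raw
  with_seed(seed, draw_outcome_labels(eta_z, config$outcome_auc_target,
                                      config$outcome_prevalence)$labels)
}

#' Write a synthetic cohort to delimited text
#'
#' Writes the participant table, cognition table and one CSV per modality
#' (`participant_id` first column, header row), plus a JSON sidecar with the
#' ground truth.
#'
#' @param sim an `lc_cohort_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "lc_cohort_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$cohort, file.path(dir, "cohort.csv"))
  readr::write_csv(sim$cognition, file.path(dir, "cognition.csv"))
  for (mod in names(sim$features)) {
    readr::write_csv(sim$features[[mod]],
                     file.path(dir, sprintf("features_%s.csv", tolower(mod))))
  }
  truth <- sim$truth
  truth_json <- list(
    planted_variance_explained = truth$planted_variance_explained,
    informative_feature_ids = truth$informative_feature_ids,
    outcome_coefficients = as.list(truth$outcome_coefficients),
    outcome_intercept = truth$outcome_intercept,
    factor_loadings_Y = truth$factor_loadings_Y,
    seed = truth$seed
  )
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
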