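#' Fit an empirical-Bayes site-harmonization model
#'
#' Removes additive (location) and multiplicative (scale) site effects from
#' a brain feature matrix while preserving covariate effects (e.g. age, sex,
#' and mean head motion for functional connectivity), the parametric
#' empirical-Bayes batch-adjustment model: per feature, a linear model with
#' site indicators plus covariates is fitted; residuals are standardized by
#' the pooled variance; per-site location and scale estimates are shrunk
#' toward pooled normal / inverse-gamma priors by iterated conditional
#' posterior means (tolerance 1e-4, capped at 100 iterations).
#'
#' Fitting is separated from application so a model trained on one sample
#' can be applied to held-out participants from the same sites, and
#' serialized for audit.
#'
#' @param features participants x features tibble/matrix (optionally with
#'   `participant_id`).
#' @param cohort participant tibble, row-aligned with `features`, holding
#'   `site` and the covariate columns.
#' @param covariates character vector of cohort columns whose effects are
#'   protected (default `c("age", "sex")`; add `"mean_fd"` for functional
#'   connectivity).
#' @param remove_covariates if `TRUE`, covariate effects are residualized
#'   out of the adjusted data instead of being restored (default `FALSE`:
#'   biology is preserved, only site effects are removed).
#' @param tol,max_iter convergence control for the EB iteration.
#' @return a `harmonization_model` object.
#' @export
fit_harmonization <- function(features, cohort, covariates = c("age", "sex"),
                              remove_covariates = FALSE,
                              tol = 1e-4, max_iter = 100L) {
  x <- as_feature_matrix(features)
  if (nrow(x) != nrow(cohort)) abort("features and cohort are not row-aligned.")
  if (!"site" %in% names(cohort)) abort("cohort must contain a `site` column.")
  miss <- setdiff(covariates, names(cohort))
  if (length(miss)) abort(paste0("covariates missing from cohort: ",
                                 paste(miss, collapse = ", ")))
  site <- factor(cohort$site)
  sites <- levels(site)
  n <- nrow(x); G <- ncol(x)
  ns <- table(site)
  if (any(ns < 2)) {
    abort(sprintf("site(s) with a single participant: %s",
                  paste(names(ns)[ns < 2], collapse = ", ")))
  }

  C <- if (length(covariates)) {
    cm <- as.matrix(as.data.frame(lapply(cohort[covariates], as.numeric)))
    colnames(cm) <- covariates
    cm
  } else {
    matrix(0, n, 0)
  }

  if (length(sites) < 2) {
    warn("single site: harmonization model is an identity adjustment.")
    model <- structure(list(identity = TRUE, sites = sites,
                            covariates = covariates,
                            feature_names = colnames(x),
                            remove_covariates = remove_covariates),
                       class = "harmonization_model")
    return(model)
  }

  B <- stats::model.matrix(~ 0 + site)
  colnames(B) <- sites
  D <- cbind(B, C)
  if (qr(D)$rank < ncol(D)) {
    abort("covariates are collinear with each other or with site.")
  }

  # per-feature OLS for all features at once
  beta <- solve(crossprod(D), crossprod(D, x))
  site_eff <- beta[seq_along(sites), , drop = FALSE]
  cov_slopes <- beta[-seq_along(sites), , drop = FALSE]
  grand <- as.numeric(crossprod(as.numeric(ns) / n, site_eff))
  resid <- x - D %*% beta
  var_pooled <- colSums(resid^2) / n

  stand_mean <- matrix(grand, n, G, byrow = TRUE) +
    (if (ncol(C)) C %*% cov_slopes else 0)
  usable <- var_pooled > 0
  z <- x * 0
  z[, usable] <- (x[, usable] - stand_mean[, usable]) /
    matrix(sqrt(var_pooled[usable]), n, sum(usable), byrow = TRUE)

  # within-site raw location/scale estimates on the standardized scale
  S <- length(sites)
  gamma_hat <- matrix(0, S, G, dimnames = list(sites, colnames(x)))
  delta_hat <- matrix(1, S, G, dimnames = list(sites, colnames(x)))
  for (s in seq_len(S)) {
    zi <- z[site == sites[s], , drop = FALSE]
    gamma_hat[s, ] <- colMeans(zi)
    delta_hat[s, ] <- apply(zi, 2, var)
  }
  zero_var <- !usable | colSums(delta_hat <= 0) > 0
  if (any(zero_var)) {
    warn(sprintf("%d feature(s) with zero within-site variance passed through unadjusted.",
                 sum(zero_var)))
  }
  est <- seq_len(G)[!zero_var]

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  iters <- integer(S)
  for (s in seq_len(S)) {
    gh <- gamma_hat[s, est]; dh <- delta_hat[s, est]
    g_bar <- mean(gh); t2 <- var(gh)
    m <- mean(dh); s2 <- var(dh)
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    zi <- z[site == sites[s], est, drop = FALSE]
    ni <- nrow(zi)
    g_old <- gh; d_old <- dh
    for (it in seq_len(max_iter)) {
      g_new <- (t2 * ni * gh + d_old * g_bar) / (t2 * ni + d_old)
      sum2 <- colSums((zi - matrix(g_new, ni, length(g_new), byrow = TRUE))^2)
      d_new <- (0.5 * sum2 + b_prior) / (ni / 2 + a_prior - 1)
      change <- max(abs(g_new - g_old) / abs(g_old),
                    abs(d_new - d_old) / abs(d_old))
      g_old <- g_new; d_old <- d_new
      if (change < tol) break
    }
    iters[s] <- it
    gamma_star[s, est] <- g_old
    delta_star[s, est] <- d_old
  }
  # pass-through features: no adjustment
  gamma_star[, zero_var] <- 0
  delta_star[, zero_var] <- 1

  structure(list(
    identity = FALSE,
    sites = sites,
    site_n = as.integer(ns),
    covariates = covariates,
    feature_names = colnames(x),
    grand_mean = grand,
    cov_slopes = cov_slopes,
    var_pooled = var_pooled,
    gamma_hat = gamma_hat,
    delta_hat = delta_hat,
    gamma_star = gamma_star,
    delta_star = delta_star,
    passthrough = colnames(x)[zero_var],
    eb_iterations = iters,
    remove_covariates = remove_covariates
  ), class = "harmonization_model")
}

#' Apply a fitted harmonization model
#'
#' Standardizes features with the training-fit grand mean, covariate slopes
#' and pooled variance, removes the posterior site location/scale effects,
#' and restores the covariate effects and grand mean (unless the model was
#' fitted with `remove_covariates = TRUE`). Deterministic; unseen site
#' labels are an error.
#'
#' @param model a `harmonization_model` from [fit_harmonization()].
#' @param features participants x features tibble/matrix.
#' @param cohort row-aligned participant tibble with `site` and the model's
#'   covariates.
#' @return adjusted feature tibble (with `participant_id` if supplied).
#' @export
apply_harmonization <- function(model, features, cohort) {
  stopifnot(inherits(model, "harmonization_model"))
  has_id <- is.data.frame(features) && "participant_id" %in% names(features)
  ids <- if (has_id) features$participant_id
  x <- as_feature_matrix(features)
  if (nrow(x) != nrow(cohort)) abort("features and cohort are not row-aligned.")
  if (!all(model$feature_names %in% colnames(x))) {
    abort("features missing columns the model was fitted on.")
  }
  x <- x[, model$feature_names, drop = FALSE]
  if (isTRUE(model$identity)) {
    out <- tibble::as_tibble(x)
    if (has_id) out <- dplyr::bind_cols(tibble::tibble(participant_id = ids), out)
    return(out)
  }
  site <- as.character(cohort$site)
  unseen <- setdiff(unique(site), model$sites)
  if (length(unseen)) {
    abort(paste0("site label(s) not seen at fit time: ",
                 paste(unseen, collapse = ", ")))
  }
  n <- nrow(x); G <- ncol(x)
  C <- if (length(model$covariates)) {
    as.matrix(as.data.frame(lapply(cohort[model$covariates], as.numeric)))
  } else {
    matrix(0, n, 0)
  }
  cov_part <- if (ncol(C)) C %*% model$cov_slopes else matrix(0, n, G)
  stand_mean <- matrix(model$grand_mean, n, G, byrow = TRUE) + cov_part
  sdv <- sqrt(model$var_pooled)
  pass <- model$feature_names %in% model$passthrough
  sdv[pass] <- 1 # pass-through features come back unchanged
  z <- (x - stand_mean) / matrix(sdv, n, G, byrow = TRUE)
  si <- match(site, model$sites)
  adj <- (z - model$gamma_star[si, , drop = FALSE]) /
    sqrt(model$delta_star[si, , drop = FALSE])
  out_mat <- adj * matrix(sdv, n, G, byrow = TRUE) + stand_mean
  if (isTRUE(model$remove_covariates)) out_mat <- out_mat - cov_part
  out_mat[, pass] <- x[, pass]
  out <- tibble::as_tibble(out_mat)
  if (has_id) out <- dplyr::bind_cols(tibble::tibble(participant_id = ids), out)
  out
}

#' One-shot site harmonization
#'
#' Convenience wrapper: fit on the supplied sample and adjust that same
#' sample.
#'
#' @inheritParams fit_harmonization
#' @return adjusted feature tibble with the fitted model in attribute
#'   `"model"`.
#' @export
harmonize <- function(features, cohort, covariates = c("age", "sex"),
                      remove_covariates = FALSE) {
  model <- fit_harmonization(features, cohort, covariates,
                             remove_covariates = remove_covariates)
  out <- apply_harmonization(model, features, cohort)
  attr(out, "model") <- model
  out
}

#' @export
print.harmonization_model <- function(x, ...) {
  if (isTRUE(x$identity)) {
    cat("<harmonization_model> identity adjustment (single site)\n")
    return(invisible(x))
  }
  cat("<harmonization_model>\n")
  cat("  sites:      ", paste(sprintf("%s (n=%d)", x$sites, x$site_n),
                              collapse = ", "), "\n")
  cat("  covariates: ", if (length(x$covariates)) paste(x$covariates, collapse = ", ")
      else "(none)", if (isTRUE(x$remove_covariates)) " [removed]" else " [protected]", "\n")
  cat("  features:   ", length(x$feature_names),
      sprintf(" (%d passed through)", length(x$passthrough)), "\n")
  invisible(x)
}

#' Serialize a harmonization model to structured text
#'
#' Writes the model parameters (grand means, covariate slopes, pooled
#' variances, per-site posterior location/scale effects) as JSON for audit.
#'
#' @param model a `harmonization_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_harmonization_model <- function(model, path) {
  stopifnot(inherits(model, "harmonization_model"))
  obj <- unclass(model)
  obj$gamma_hat <- NULL; obj$delta_hat <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
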