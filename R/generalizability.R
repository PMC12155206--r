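#' Composite cognitive variable by principal component analysis
#'
#' First principal component of a selected set of cognitive tests (those
#' significantly associated with the brain latent variables), with the sign
#' fixed so the composite correlates positively with the mean of the
#' selected tests. With a single selected test the standardized test itself
#' is returned with a warning.
#'
#' @param Y participants x tests tibble/matrix.
#' @param selected_tests character vector of test columns to combine.
#' @return a `cognitive_composite`: `scores`, `weights`, the selected test
#'   list and the centering/scaling used (so the composite can be projected
#'   onto held-out data).
#' @export
composite_cognition <- function(Y, selected_tests) {
  Ym <- as_feature_matrix(Y)
  miss <- setdiff(selected_tests, colnames(Ym))
  if (length(miss)) abort(paste0("selected tests not in Y: ",
                                 paste(miss, collapse = ", ")))
  if (length(selected_tests) < 1) abort("no tests selected.")
  sel <- Ym[, selected_tests, drop = FALSE]
  ctr <- colMeans(sel); scl <- apply(sel, 2, sd)
  if (any(scl <= 0)) abort("constant test among the selected columns.")
  if (length(selected_tests) == 1L) {
    warn("single selected test: composite is that test, standardized.")
    w <- setNames(1, selected_tests)
    scores <- as.numeric((sel - ctr) / scl)
    return(structure(list(scores = scores, weights = w,
                          tests = selected_tests, center = ctr, scale = scl),
                     class = "cognitive_composite"))
  }
  pc <- prcomp(sel, center = TRUE, scale. = TRUE)
  w <- pc$rotation[, 1L]
  scores <- pc$x[, 1L]
  zsel <- sweep(sweep(sel, 2, ctr, "-"), 2, scl, "/")
  if (cor(scores, rowMeans(zsel)) < 0) {
    w <- -w; scores <- -scores
  }
  structure(list(scores = as.numeric(scores), weights = w,
                 tests = selected_tests, center = ctr, scale = scl),
            class = "cognitive_composite")
}

#' Project a fitted composite onto new cognition data
#'
#' Standardizes the selected tests with the training centering/scaling and
#' applies the training PCA weights.
#'
#' @param composite a `cognitive_composite`.
#' @param Y new participants x tests tibble/matrix.
#' @return numeric composite scores.
#' @export
project_composite <- function(composite, Y) {
  stopifnot(inherits(composite, "cognitive_composite"))
  Ym <- as_feature_matrix(Y)
  sel <- Ym[, composite$tests, drop = FALSE]
  z <- sweep(sweep(sel, 2, composite$center, "-"), 2, composite$scale, "/")
  as.numeric(z %*% composite$weights)
}

#' Leave-one-site-out generalizability of a PLS brain-cognition model
#'
#' For each site: z-score training X and Y (training parameters only), fit
#' the PLS model, select the cognitive tests significantly associated with
#' the training latent scores (Bonferroni), build a PCA composite of those
#' tests on training data, then standardize the held-out site with the
#' training scalers, predict its cognition through the training
#' beta-coefficient matrix, and correlate predicted with observed composite
#' cognition. No information flows from the held-out site into training.
#'
#' @param X participants x features tibble/matrix (pre-harmonized).
#' @param Y participants x tests tibble/matrix (imputed).
#' @param sites per-participant site labels.
#' @param n_components `"auto"` (sequential permutation on training data) or
#'   a fixed integer.
#' @param max_components cap for the auto rule.
#' @param n_perm permutations for the auto rule.
#' @param alpha level for the component rule and test selection.
#' @param fixed_test_list optional fixed test set (bypasses within-fold test
#'   selection; mirrors analyses that reuse a full-sample test list).
#' @param min_site_n sites smaller than this are skipped with a warning.
#' @param seed integer seed.
#' @return a `loso_result`: per-site tibble (site, n_test, n_components,
#'   tests selected, held-out r, p) plus fold details.
#' @export
leave_one_site_out <- function(X, Y, sites, n_components = "auto",
                               max_components = 3, n_perm = 200, alpha = 0.05,
                               fixed_test_list = NULL, min_site_n = 3,
                               seed = NULL) {
  Xm <- as_feature_matrix(X); Ym <- as_feature_matrix(Y)
  sites <- as.character(sites)
  stopifnot(nrow(Xm) == length(sites), nrow(Ym) == length(sites))
  usite <- sort(unique(sites))
  if (length(usite) < 2) abort("need at least 2 sites.")
  rows <- list(); folds <- list()
  for (s in usite) {
    test_idx <- which(sites == s)
    if (length(test_idx) < min_site_n) {
      warn(sprintf("site %s has fewer than %d participants; skipped.",
                   s, min_site_n))
      next
    }
    train_idx <- which(sites != s)
    Xtr <- zscore_columns(Xm[train_idx, , drop = FALSE])
    Ytr <- zscore_columns(Ym[train_idx, , drop = FALSE])
    fold_seed <- if (is.null(seed)) NULL else derive_seed(seed, paste0("loso_", s))
    k <- if (identical(n_components, "auto")) {
      max(1L, select_n_components(Xtr, Ytr, max_components = max_components,
                                  n_perm = n_perm, alpha = alpha,
                                  seed = fold_seed))
    } else {
      as.integer(n_components)
    }
    fit <- fit_pls(Xtr, Ytr, n_components = k, check = FALSE)
    sel <- fixed_test_list
    if (is.null(sel)) {
      ltc <- latent_test_correlations(fit, Ytr, alpha = alpha)
      sel <- unique(ltc$test[ltc$significant])
      if (length(sel) == 0L) {
        warn(sprintf("site %s fold: no significant tests; using all tests.", s))
        sel <- colnames(as_feature_matrix(Ytr))
      }
    }
    comp <- suppressWarnings(composite_cognition(Ytr, sel))
    x_scaler <- zscore_params(Xtr); y_scaler <- zscore_params(Ytr)
    Xte <- apply_zscore(Xm[test_idx, , drop = FALSE], x_scaler)
    Yte <- apply_zscore(Ym[test_idx, , drop = FALSE], y_scaler)
    pred_y <- predict(fit, Xte)
    pred_comp <- project_composite(comp, pred_y)
    obs_comp <- project_composite(comp, Yte)
    ct <- if (sd(pred_comp) > 0 && sd(obs_comp) > 0) {
      cor.test(pred_comp, obs_comp)
    } else {
      list(estimate = NA_real_, p.value = NA_real_)
    }
    rows[[s]] <- tibble::tibble(
      site = s, n_test = length(test_idx), n_components = k,
      n_tests_selected = length(sel), r = unname(ct$estimate),
      p = ct$p.value)
    folds[[s]] <- list(fit = fit, composite = comp, tests = sel,
                       predicted = pred_comp, observed = obs_comp)
  }
  if (!length(rows)) abort("no site large enough to hold out.")
  structure(list(by_site = dplyr::bind_rows(rows), folds = folds,
                 n_components = n_components, seed = seed),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat("<loso_result>\n")
  print(x$by_site)
  cat(sprintf("  mean held-out r = %.3f\n", mean(x$by_site$r, na.rm = TRUE)))
  invisible(x)
}
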