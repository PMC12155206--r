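# Core NIPALS machinery. Per component the weight vector is the dominant
# direction of the X'Y cross-covariance (the NIPALS fixed point), obtained
# exactly from the small q x q Gram eigenproblem so near-degenerate spectra
# (null data) cannot stall a power iteration. X is deflated by its loading
# rank-1 term; Y is not deflated (regression mode).
.pls_weight <- function(S) {
  if (ncol(S) == 1L) {
    w <- S[, 1L]
  } else {
    G <- crossprod(S)
    v <- eigen(G, symmetric = TRUE)$vectors[, 1L]
    w <- as.numeric(S %*% v)
  }
  nrm <- sqrt(sum(w^2))
  if (nrm <= 0) abort("degenerate cross-covariance: all-zero X'Y.")
  w <- w / nrm
  # sign convention: largest-magnitude weight element positive
  if (w[which.max(abs(w))] < 0) w <- -w
  w
}

.pls_core <- function(X, Y, ncomp, keep_scores = FALSE) {
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); Q <- matrix(0, q, ncomp)
  TT <- if (keep_scores) matrix(0, n, ncomp) else NULL
  tt <- numeric(ncomp)
  ssy <- sum(Y^2)
  varexp <- numeric(ncomp)
  Xd <- X
  for (h in seq_len(ncomp)) {
    S <- crossprod(Xd, Y)
    w <- .pls_weight(S)
    t_h <- as.numeric(Xd %*% w)
    tth <- sum(t_h^2)
    if (tth <= .Machine$double.eps * n) {
      abort(sprintf("component %d exceeds the rank of X.", h))
    }
    p_h <- as.numeric(crossprod(Xd, t_h)) / tth
    q_h <- as.numeric(crossprod(Y, t_h)) / tth
    Xd <- Xd - tcrossprod(t_h, p_h)
    W[, h] <- w; P[, h] <- p_h; Q[, h] <- q_h; tt[h] <- tth
    if (keep_scores) TT[, h] <- t_h
    varexp[h] <- sum(q_h^2) * tth / ssy
  }
  list(W = W, P = P, Q = Q, scores = TT, tt = tt, varexp = varexp,
       total_varexp = sum(varexp))
}

.pls_beta <- function(W, P, Q) {
  # direct-projection weights W* = W (P'W)^{-1}; B maps standardized X to
  # fitted standardized Y
  Wstar <- W %*% solve(crossprod(P, W))
  Wstar %*% t(Q)
}

#' Fit a partial least squares (PLS) regression
#'
#' Links a brain feature matrix X to a cognition matrix Y through
#' `n_components` paired latent variables that maximize cross-block
#' covariance (NIPALS, regression mode: X is deflated component by
#' component, Y is not). Both blocks must be column-standardized (z-scored);
#' use [zscore_columns()]. The per-component weight vector is the dominant
#' direction of the current X'Y cross-covariance, with the sign fixed so the
#' largest-magnitude weight element is positive.
#'
#' @param X participants x features matrix/tibble, z-scored.
#' @param Y participants x tests matrix/tibble, z-scored.
#' @param n_components number of latent variables.
#' @param check verify standardization and rank preconditions
#'   (default `TRUE`; resampling loops disable it internally).
#' @param tol tolerance on column means/SDs for the standardization check.
#' @return a `pls_fit` with x_weights, x_loadings, y_loadings, x_scores
#'   (XS), y_scores, the X->Y coefficient matrix `beta`, and per-component /
#'   cumulative fractions of Y-variance explained.
#' @examples
#' set.seed(1)
#' X <- zscore_columns(matrix(rnorm(200), 20, 10))
#' Y <- zscore_columns(matrix(rnorm(60), 20, 3))
#' fit <- fit_pls(X, Y, n_components = 2)
#' glance(fit)
#' @export
fit_pls <- function(X, Y, n_components, check = TRUE, tol = 1e-6) {
  Xm <- as_feature_matrix(X); Ym <- as_feature_matrix(Y)
  if (nrow(Xm) != nrow(Ym)) abort("X and Y are not row-aligned.")
  n <- nrow(Xm)
  if (check) {
    bad_mean <- c(abs(colMeans(Xm)), abs(colMeans(Ym))) > tol
    if (any(bad_mean)) {
      abort("input is not column-standardized (nonzero column mean); z-score first.")
    }
    if (n_components > min(qr(Xm)$rank, ncol(Ym))) {
      abort("n_components exceeds min(rank(X), ncol(Y)).")
    }
  }
  if (n_components < 1) abort("n_components must be >= 1.")
  core <- .pls_core(Xm, Ym, n_components, keep_scores = TRUE)
  beta <- .pls_beta(core$W, core$P, core$Q)
  dimnames(beta) <- list(colnames(Xm), colnames(Ym))
  comp_names <- paste0("LV", seq_len(n_components))
  dimnames(core$W) <- dimnames(core$P) <- list(colnames(Xm), comp_names)
  dimnames(core$Q) <- list(colnames(Ym), comp_names)
  colnames(core$scores) <- comp_names
  # y-side scores: projections of Y on each component's y-loading
  U <- Ym %*% sweep(core$Q, 2, colSums(core$Q^2), "/")
  colnames(U) <- comp_names
  structure(list(
    n_components = n_components,
    x_weights = core$W,
    x_loadings = core$P,
    y_loadings = core$Q,
    x_scores = core$scores,
    y_scores = U,
    beta = beta,
    score_ss = core$tt,
    variance_explained = tibble::tibble(
      component = comp_names,
      proportion = core$varexp,
      cumulative = cumsum(core$varexp)),
    total_variance_explained = core$total_varexp,
    dims = c(n = n, p = ncol(Xm), q = ncol(Ym))
  ), class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  d <- x$dims
  cat(sprintf("<pls_fit> %d latent variable(s), n=%d, p=%d, q=%d\n",
              x$n_components, d["n"], d["p"], d["q"]))
  cat(sprintf("  Y-variance explained: %.1f%% (per component: %s)\n",
              100 * x$total_variance_explained,
              paste(sprintf("%.1f%%", 100 * x$variance_explained$proportion),
                    collapse = ", ")))
  invisible(x)
}

#' Predict cognition from a fitted PLS model
#'
#' @param object a `pls_fit`.
#' @param newdata standardized feature matrix/tibble (use the training
#'   scaler via [apply_zscore()]).
#' @param ... unused.
#' @return tibble of predicted (standardized-scale) Y columns.
#' @export
predict.pls_fit <- function(object, newdata, ...) {
  Xm <- as_feature_matrix(newdata)
  if (!is.null(rownames(object$beta)) && !is.null(colnames(Xm))) {
    if (!all(rownames(object$beta) %in% colnames(Xm))) {
      abort("newdata is missing features the model was trained on.")
    }
    Xm <- Xm[, rownames(object$beta), drop = FALSE]
  }
  tibble::as_tibble(Xm %*% object$beta)
}

#' Permutation test of PLS model significance
#'
#' Refits the model on row-permuted Y and records the total fraction of
#' Y-variance explained; the p-value is `(1 + #permuted >= observed) /
#' (n_perm + 1)` (the +1 correction keeps p in (0, 1]).
#'
#' @inheritParams fit_pls
#' @param n_perm number of permutations (study-scale default 5000; reduce
#'   for exploration).
#' @param seed integer seed for the permutation stream.
#' @return a `pls_permutation` with the observed statistic, the null
#'   distribution, and the p-value.
#' @export
permutation_test <- function(X, Y, n_components, n_perm = 5000, seed = NULL) {
  if (n_perm < 1) abort("n_perm must be >= 1.")
  Xm <- as_feature_matrix(X); Ym <- as_feature_matrix(Y)
  observed <- .pls_core(Xm, Ym, n_components)$total_varexp
  n <- nrow(Xm)
  null_dist <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    .pls_core(Xm, Ym[sample.int(n), , drop = FALSE], n_components)$total_varexp
  }, numeric(1)))
  structure(list(
    observed_statistic = observed,
    null_distribution = null_dist,
    p_value = (1 + sum(null_dist >= observed)) / (n_perm + 1),
    n_perm = n_perm,
    n_components = n_components,
    seed = seed
  ), class = "pls_permutation")
}

#' @export
print.pls_permutation <- function(x, ...) {
  cat(sprintf("<pls_permutation> observed varexp = %.4f, p = %.4g (n_perm = %d)\n",
              x$observed_statistic, x$p_value, x$n_perm))
  invisible(x)
}

#' Permutation-debiased variance explained
#'
#' In-sample PLS variance explained is upward-biased: even null data yield a
#' positive maximum-covariance component. Subtracting the mean of the
#' permutation null distribution gives a bias-corrected estimate of the
#' Y-variance genuinely explained by X, suitable for parameter-recovery
#' comparisons against a known planted value.
#'
#' @param fit a `pls_fit`.
#' @param permutation the matching `pls_permutation` (same data and
#'   component count).
#' @return numeric debiased fraction of Y-variance explained.
#' @export
variance_explained_debiased <- function(fit, permutation) {
  stopifnot(inherits(fit, "pls_fit"), inherits(permutation, "pls_permutation"))
  if (fit$n_components != permutation$n_components) {
    abort("fit and permutation use different component counts.")
  }
  fit$total_variance_explained - mean(permutation$null_distribution)
}

#' Choose the number of PLS components by sequential permutation
#'
#' Components are retained while each one adds permutation-significant
#' covariance: at step k the first component of the current (deflated X,
#' residualized Y) pair is tested against row permutations of the residual
#' Y at level `alpha`; on success X is deflated and Y residualized, and the
#' next component is tested. Returns the retained count (possibly 0).
#'
#' @inheritParams permutation_test
#' @param max_components largest count considered.
#' @param alpha per-step significance level (default 0.05).
#' @return integer number of retained components.
#' @export
select_n_components <- function(X, Y, max_components, n_perm = 200,
                                alpha = 0.05, seed = NULL) {
  if (max_components < 1) abort("max_components must be >= 1.")
  Xd <- as_feature_matrix(X); Yd <- as_feature_matrix(Y)
  n <- nrow(Xd)
  with_seed(seed, {
    k <- 0L
    for (step in seq_len(max_components)) {
      one <- .pls_core(Xd, Yd, 1L)
      null_dist <- vapply(seq_len(n_perm), function(i) {
        .pls_core(Xd, Yd[sample.int(n), , drop = FALSE], 1L)$total_varexp
      }, numeric(1))
      p <- (1 + sum(null_dist >= one$total_varexp)) / (n_perm + 1)
      if (p >= alpha) break
      k <- step
      t_h <- Xd %*% one$W[, 1L]
      Xd <- Xd - tcrossprod(as.numeric(t_h), one$P[, 1L])
      Yd <- Yd - tcrossprod(as.numeric(t_h), one$Q[, 1L])
    }
    k
  })
}

#' Bootstrap ratios for PLS loading robustness
#'
#' Resamples participants with replacement, re-standardizes and refits,
#' aligns each replicate's components to the original fit (order and sign by
#' maximal absolute correlation between replicate-projected and original
#' X-scores), and accumulates each X-loading's bootstrap mean and standard
#' error. The bootstrap ratio Z = mean / SE; features with |Z| > `z_threshold`
#' (default 3) are flagged as robust contributors.
#'
#' @inheritParams permutation_test
#' @param n_boot number of bootstrap resamples (study-scale default 5000).
#' @param z_threshold robustness threshold on |Z| (default 3).
#' @param max_retries redraw budget for degenerate (zero-variance) resamples.
#' @return a `pls_bootstrap` with `z_ratio` (features x components) and the
#'   significance mask.
#' @export
bootstrap_loadings <- function(X, Y, n_components, n_boot = 5000, seed = NULL,
                               z_threshold = 3, max_retries = 10L) {
  Xm <- as_feature_matrix(X); Ym <- as_feature_matrix(Y)
  n <- nrow(Xm)
  orig <- .pls_core(Xm, Ym, n_components, keep_scores = TRUE)
  orig_scores <- orig$scores
  p <- ncol(Xm)
  sum_l <- matrix(0, p, n_components)
  sum_l2 <- matrix(0, p, n_components)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      for (attempt in seq_len(max_retries)) {
        idx <- sample.int(n, n, replace = TRUE)
        Xb <- Xm[idx, , drop = FALSE]; Yb <- Ym[idx, , drop = FALSE]
        sx <- apply(Xb, 2, sd); sy <- apply(Yb, 2, sd)
        if (all(sx > 0) && all(sy > 0)) break
        if (attempt == max_retries) {
          abort("could not draw a non-degenerate bootstrap resample.")
        }
      }
      Xb <- scale(Xb); Yb <- scale(Yb)
      fb <- .pls_core(Xb, Yb, n_components, keep_scores = FALSE)
      # replicate scores on the original sample, for alignment
      proj <- Xm %*% (fb$W %*% solve(crossprod(fb$P, fb$W)))
      cors <- suppressWarnings(cor(proj, orig_scores))
      cors[!is.finite(cors)] <- 0
      perm <- integer(n_components); signs <- numeric(n_components)
      avail <- rep(TRUE, n_components)
      for (h in seq_len(n_components)) {
        j <- which.max(ifelse(avail, abs(cors[, h]), -Inf))
        perm[h] <- j; signs[h] <- sign(cors[j, h] + (cors[j, h] == 0))
        avail[j] <- FALSE
      }
      Pb <- sweep(fb$P[, perm, drop = FALSE], 2, signs, "*")
      sum_l <- sum_l + Pb
      sum_l2 <- sum_l2 + Pb^2
    }
  })
  bmean <- sum_l / n_boot
  bse <- sqrt(pmax(sum_l2 / n_boot - bmean^2, 0) * n_boot / (n_boot - 1))
  z <- bmean / bse
  z[bse == 0] <- 0
  dimnames(z) <- list(colnames(Xm), paste0("LV", seq_len(n_components)))
  structure(list(
    z_ratio = z,
    significant_mask = abs(z) > z_threshold,
    bootstrap_mean = bmean,
    bootstrap_se = bse,
    original_loadings = orig$P,
    z_threshold = z_threshold,
    n_boot = n_boot,
    seed = seed
  ), class = "pls_bootstrap")
}

#' @export
print.pls_bootstrap <- function(x, ...) {
  cat(sprintf("<pls_bootstrap> n_boot = %d, |Z| > %g\n", x$n_boot, x$z_threshold))
  cat("  robust features per component:",
      paste(colSums(x$significant_mask), collapse = ", "), "\n")
  invisible(x)
}

#' Correlate latent brain scores with cognitive tests
#'
#' Pearson correlation of each X-score column (XS) with each cognitive test,
#' with Bonferroni correction over the (components x tests) family.
#' A constant test column yields an undefined correlation and is flagged
#' not-significant with a warning.
#'
#' @param fit a `pls_fit`.
#' @param Y_raw participants x tests tibble/matrix, row-aligned with the
#'   data the model was fitted on.
#' @param alpha family-wise level (default 0.05).
#' @return tibble: component, test, r, p, p_bonferroni, significant.
#' @export
latent_test_correlations <- function(fit, Y_raw, alpha = 0.05) {
  stopifnot(inherits(fit, "pls_fit"))
  Ym <- as_feature_matrix(Y_raw)
  XS <- fit$x_scores
  if (nrow(Ym) != nrow(XS)) abort("Y_raw is not row-aligned with the fit.")
  n <- nrow(Ym)
  const <- apply(Ym, 2, sd) == 0
  if (any(const)) {
    warn(sprintf("constant test column(s): %s; flagged not-significant.",
                 paste(colnames(Ym)[const], collapse = ", ")))
  }
  grid <- expand.grid(component = colnames(XS), test = colnames(Ym),
                      stringsAsFactors = FALSE)
  m <- nrow(grid)
  r <- mapply(function(cc, tt) {
    if (const[tt]) return(NA_real_)
    cor(XS[, cc], Ym[, tt])
  }, grid$component, grid$test)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  praw <- 2 * pt(-abs(tstat), df = n - 2)
  tibble::tibble(
    component = grid$component,
    test = grid$test,
    r = as.numeric(r),
    p = as.numeric(praw),
    p_bonferroni = pmin(as.numeric(praw) * m, 1),
    significant = !is.na(praw) & praw * m < alpha
  )
}

#' Association of latent scores with a covariate
#'
#' Pearson correlation with a two-sided p-value — the follow-up test used to
#' relate PLS cognitive scores to education, brain-structure centile, prior
#' treatment resistance (ATHF) or white-matter hyperintensity burden.
#'
#' @param latent_scores numeric vector of per-participant latent scores.
#' @param covariate aligned numeric covariate vector.
#' @return one-row tibble: estimate (r), p.value, n.
#' @export
association_with_covariate <- function(latent_scores, covariate) {
  if (length(latent_scores) != length(covariate)) abort("length mismatch.")
  ok <- complete.cases(latent_scores, covariate)
  if (sum(ok) < 4) abort("need at least 4 complete pairs.")
  if (sd(latent_scores[ok]) == 0 || sd(covariate[ok]) == 0) {
    abort("constant input: correlation undefined.")
  }
  ct <- cor.test(latent_scores[ok], covariate[ok])
  tibble::tibble(estimate = unname(ct$estimate), p.value = ct$p.value,
                 n = sum(ok))
}
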