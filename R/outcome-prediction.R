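#' Iterated nested cross-validated elastic-net prediction of remission
#'
#' On each of `n_iter` iterations the sample is split into a training set
#' and a held-out test set of `test_n` participants (stratified by outcome).
#' Inside the training split, stratified `inner_folds`-fold cross-validation
#' selects the elastic-net penalty (mixing parameter x shrinkage grid) by
#' maximum mean inner AUC; the model refitted on the full training split is
#' evaluated on the held-out participants. Feature standardization happens
#' inside each training split only. Per-feature stability frequencies — the
#' fraction of iterations in which a feature survives regularization with a
#' nonzero coefficient — support parsimonious model selection via
#' [stability_select()].
#'
#' @param features participants x predictors tibble/matrix (demographic,
#'   clinical, cognitive and/or brain-structure columns).
#' @param labels binary remission labels (e.g. endpoint MADRS <= 10).
#' @param n_iter number of outer iterations (default 100).
#' @param test_n held-out participants per iteration (default 20).
#' @param inner_folds inner CV folds (default 10).
#' @param alpha_grid elastic-net mixing parameters (default 0.1, 0.5, 0.9).
#' @param n_lambda log-spaced shrinkage values per mixing parameter
#'   (default 20).
#' @param seed integer seed; fully determines the splits.
#' @return a `prediction_run`: per-iteration tibble (selected penalty,
#'   nonzero set, held-out AUC), stability frequencies, and the mean /
#'   percentile interval of held-out AUC.
#' @export
nested_elasticnet <- function(features, labels, n_iter = 100, test_n = 20,
                              inner_folds = 10, alpha_grid = c(0.1, 0.5, 0.9),
                              n_lambda = 20, seed = NULL) {
  Xall <- as_feature_matrix(features)
  y <- as_binary01(labels)
  n <- nrow(Xall)
  if (length(y) != n) abort("features and labels are not aligned.")
  tab <- table(y)
  if (length(tab) < 2 || any(tab < test_n)) {
    abort("each outcome class must have at least test_n participants.")
  }
  p <- ncol(Xall)
  nz_counts <- setNames(numeric(p), colnames(Xall))
  iters <- vector("list", n_iter)
  with_seed(seed, {
    for (i in seq_len(n_iter)) {
      # stratified outer split: test_n held out, class balance preserved
      n_pos <- max(1L, round(test_n * mean(y)))
      n_neg <- test_n - n_pos
      test_idx <- c(sample(which(y == 1L), n_pos),
                    sample(which(y == 0L), n_neg))
      train_idx <- setdiff(seq_len(n), test_idx)
      Xtr <- Xall[train_idx, , drop = FALSE]; ytr <- y[train_idx]
      foldid <- stratified_folds(ytr, inner_folds)
      best <- list(auc = -Inf)
      for (a in alpha_grid) {
        cvfit <- glmnet::cv.glmnet(Xtr, ytr, family = "binomial",
                                   type.measure = "auc", alpha = a,
                                   nlambda = n_lambda, foldid = foldid,
                                   standardize = TRUE)
        j <- which.max(cvfit$cvm)
        if (cvfit$cvm[j] > best$auc) {
          best <- list(auc = cvfit$cvm[j], alpha = a,
                       lambda = cvfit$lambda[j], fit = cvfit)
        }
      }
      co <- as.numeric(coef(best$fit, s = best$lambda))[-1L]
      sel <- colnames(Xall)[co != 0]
      nz_counts[sel] <- nz_counts[sel] + 1
      prob <- as.numeric(predict(best$fit, Xall[test_idx, , drop = FALSE],
                                 s = best$lambda, type = "response"))
      auc_i <- if (length(unique(y[test_idx])) > 1L) {
        auc_rank(y[test_idx], prob)
      } else {
        NA_real_ # single-class test draw: AUC undefined, excluded from mean
      }
      iters[[i]] <- tibble::tibble(
        iteration = i, alpha = best$alpha, lambda = best$lambda,
        inner_cv_auc = best$auc, n_nonzero = length(sel),
        holdout_auc = auc_i, selected = list(sel),
        test_ids = list(test_idx))
    }
  })
  iter_tbl <- dplyr::bind_rows(iters)
  aucs <- iter_tbl$holdout_auc[!is.na(iter_tbl$holdout_auc)]
  structure(list(
    iterations = iter_tbl,
    stability = tibble::tibble(feature = names(nz_counts),
                               frequency = nz_counts / n_iter) |>
      dplyr::arrange(dplyr::desc(.data$frequency)),
    mean_auc = mean(aucs),
    auc_interval = quantile(aucs, c(0.025, 0.975), names = FALSE),
    n_iter = n_iter, test_n = test_n, inner_folds = inner_folds,
    alpha_grid = alpha_grid, seed = seed
  ), class = "prediction_run")
}

#' @export
print.prediction_run <- function(x, ...) {
  cat(sprintf("<prediction_run> %d iterations, %d held out per iteration\n",
              x$n_iter, x$test_n))
  cat(sprintf("  mean held-out AUC = %.3f [%.3f, %.3f]\n",
              x$mean_auc, x$auc_interval[1], x$auc_interval[2]))
  top <- head(x$stability, 5)
  cat("  top stability:",
      paste(sprintf("%s (%.2f)", top$feature, top$frequency), collapse = ", "),
      "\n")
  invisible(x)
}

#' Stability-selected parsimonious feature set
#'
#' Features that survive regularization (nonzero elastic-net coefficient at
#' the inner-CV-selected penalty) in strictly more than `threshold` of the
#' iterations — "over 95%" by default, so a feature selected in exactly 95
#' of 100 runs is *not* retained.
#'
#' @param run a `prediction_run`.
#' @param threshold stability threshold (default 0.95).
#' @return character vector of features, ordered by decreasing frequency;
#'   empty (with a warning) when nothing is stable.
#' @export
stability_select <- function(run, threshold = 0.95) {
  stopifnot(inherits(run, "prediction_run"))
  tbl <- dplyr::arrange(run$stability, dplyr::desc(.data$frequency))
  keep <- tbl$frequency > threshold
  if (!any(keep)) {
    warn("no feature exceeds the stability threshold; returning empty set.")
    return(character(0))
  }
  tbl$feature[keep]
}

#' Evaluate a parsimonious model by stratified k-fold cross-validation
#'
#' Unpenalized logistic regression on the stability-selected feature subset,
#' evaluated by pooled out-of-fold probabilities: AUC plus a confusion
#' matrix at the 0.5 probability threshold (Youden-optimal threshold
#' available via `threshold = "youden"`). Folds with quasi-separation fall
#' back to a lightly ridge-stabilized fit.
#'
#' @param features participants x predictors for the selected subset.
#' @param labels binary outcome.
#' @param k_folds number of folds (the parsimonious models are evaluated in
#'   even 8-fold and 5-fold splits in the two treatment steps).
#' @param seed integer seed for fold assignment.
#' @param threshold `0.5`-style fixed probability cutoff (default) or
#'   `"youden"`.
#' @return a `parsimonious_eval`: `auc`, `confusion` (TP/FP/TN/FN,
#'   sensitivity, specificity), pooled out-of-fold probabilities.
#' @export
evaluate_parsimonious <- function(features, labels, k_folds = 8, seed = NULL,
                                  threshold = 0.5) {
  Xm <- as_feature_matrix(features)
  y <- as_binary01(labels)
  if (ncol(Xm) < 1) abort("empty feature subset.")
  if (k_folds < 2) abort("k_folds must be >= 2.")
  prob <- rep(NA_real_, length(y))
  ridge_folds <- 0L
  with_seed(seed, {
    foldid <- stratified_folds(y, k_folds)
    for (k in seq_len(k_folds)) {
      tr <- foldid != k; te <- !tr
      df_tr <- data.frame(y = y[tr], Xm[tr, , drop = FALSE])
      fit <- withCallingHandlers(
        glm(y ~ ., data = df_tr, family = binomial()),
        warning = function(w) invokeRestart("muffleWarning"))
      if (!fit$converged || any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)) {
        # quasi-separation: lightly ridge-stabilized fallback
        ridge_folds <- ridge_folds + 1L
        rf <- glmnet::glmnet(cbind(Xm[tr, , drop = FALSE], 0), y[tr],
                             family = "binomial", alpha = 0, lambda = 1e-3)
        prob[te] <- as.numeric(predict(rf, cbind(Xm[te, , drop = FALSE], 0),
                                        type = "response"))
      } else {
        prob[te] <- predict(fit, data.frame(Xm[te, , drop = FALSE]),
                             type = "response")
      }
    }
  })
  if (ridge_folds > 0) {
    inform(sprintf("%d fold(s) used the ridge-stabilized fallback.", ridge_folds))
  }
  auc <- auc_rank(y, prob)
  cut <- if (identical(threshold, "youden")) {
    ths <- sort(unique(prob))
    yd <- vapply(ths, function(t) {
      pred <- prob >= t
      mean(pred[y == 1L]) + mean(!pred[y == 0L]) - 1
    }, numeric(1))
    ths[which.max(yd)]
  } else {
    threshold
  }
  pred <- as.integer(prob >= cut)
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  tn <- sum(pred == 0L & y == 0L); fn <- sum(pred == 0L & y == 1L)
  structure(list(
    auc = auc,
    confusion = tibble::tibble(
      TP = tp, FP = fp, TN = tn, FN = fn,
      sensitivity = tp / (tp + fn), specificity = tn / (tn + fp)),
    probabilities = prob, threshold = cut, k_folds = k_folds,
    features = colnames(Xm), ridge_folds = ridge_folds
  ), class = "parsimonious_eval")
}

#' @export
print.parsimonious_eval <- function(x, ...) {
  cat(sprintf("<parsimonious_eval> %d-fold CV, AUC = %.3f\n", x$k_folds, x$auc))
  print(x$confusion)
  invisible(x)
}

#' PLS model of continuous symptom change
#'
#' Models change in depression severity (MADRS change) from a combined
#' clinical/demographic/cognitive/brain-structure predictor block with a
#' single-outcome PLS regression, reporting in-sample variance explained, a
#' permutation p-value, and the correlation between predicted and observed
#' change in a random held-out split.
#'
#' @param features participants x predictors tibble/matrix.
#' @param outcome continuous change scores, aligned with `features`.
#' @param n_components number of latent variables (default 1).
#' @param n_perm permutations for model significance.
#' @param holdout_frac fraction held out for the random-split evaluation.
#' @param seed integer seed.
#' @return list: `fit` (a `pls_fit`), `variance_explained`, `permutation`
#'   (a `pls_permutation`), `holdout_r`, `holdout_n`.
#' @export
pls_madrs_change <- function(features, outcome, n_components = 1,
                             n_perm = 1000, holdout_frac = 0.25, seed = NULL) {
  Xm <- as_feature_matrix(features)
  stopifnot(length(outcome) == nrow(Xm))
  if (anyNA(outcome)) {
    keep <- !is.na(outcome)
    inform(sprintf("%d rows without an observed endpoint excluded.",
                   sum(!keep)))
    Xm <- Xm[keep, , drop = FALSE]; outcome <- outcome[keep]
  }
  n <- nrow(Xm)
  Xz <- zscore_columns(Xm)
  Yz <- zscore_columns(matrix(outcome, ncol = 1,
                              dimnames = list(NULL, "madrs_change")))
  fit <- fit_pls(Xz, Yz, n_components = n_components, check = FALSE)
  perm <- permutation_test(Xz, Yz, n_components = n_components,
                           n_perm = n_perm,
                           seed = if (is.null(seed)) NULL else derive_seed(seed, "perm"))
  holdout <- with_seed(
    if (is.null(seed)) NULL else derive_seed(seed, "holdout"), {
      te <- sample.int(n, max(2L, round(holdout_frac * n)))
      tr <- setdiff(seq_len(n), te)
      Xtr <- zscore_columns(Xm[tr, , drop = FALSE])
      Ytr <- zscore_columns(matrix(outcome[tr], ncol = 1,
                                   dimnames = list(NULL, "madrs_change")))
      f <- fit_pls(Xtr, Ytr, n_components = n_components, check = FALSE)
      Xte <- apply_zscore(Xm[te, , drop = FALSE], zscore_params(Xtr))
      pred <- predict(f, Xte)[[1]]
      list(r = cor(pred, outcome[te]), n = length(te))
    })
  list(fit = fit,
       variance_explained = fit$total_variance_explained,
       permutation = perm,
       holdout_r = holdout$r,
       holdout_n = holdout$n)
}
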