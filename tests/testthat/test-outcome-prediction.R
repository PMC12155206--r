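test_that("rank AUC matches the reference implementation and tie convention", {
  set.seed(81)
  y <- rbinom(200, 1, 0.4)
  s <- rnorm(200) + y
  expect_equal(auc_rank(y, s),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))))
  # constant scores: rank-based AUC with tie correction is exactly 0.5
  expect_equal(auc_rank(y, rep(0.3, 200)), 0.5)
  # perfect separation
  expect_equal(auc_rank(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  # invariance to strictly monotone transforms of the scores
  expect_equal(auc_rank(y, plogis(3 * s - 1)), auc_rank(y, s))
  expect_error(auc_rank(rep(1, 5), rnorm(5)), "single class")
})

test_that("separable labels give near-perfect held-out AUC", {
  set.seed(82)
  n <- 150
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- as.integer(X[, 1] + X[, 2] > 0)
  run <- nested_elasticnet(X, y, n_iter = 10, test_n = 20, seed = 83)
  expect_gte(run$mean_auc, 0.95)
  top <- run$stability$feature[run$stability$frequency == 1]
  expect_true(all(c("f1", "f2") %in% top))
})

test_that("shuffled labels give chance-level AUC", {
  set.seed(84)
  n <- 200
  X <- matrix(rnorm(n * 30), n, 30, dimnames = list(NULL, paste0("f", 1:30)))
  y <- rbinom(n, 1, 0.5)
  run <- nested_elasticnet(X, y, n_iter = 20, test_n = 20, seed = 85)
  expect_gt(run$mean_auc, 0.38)
  expect_lt(run$mean_auc, 0.62)
})

test_that("runs are deterministic given the seed", {
  set.seed(86)
  X <- matrix(rnorm(120 * 8), 120, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- as.integer(X[, 1] > -0.2)
  r1 <- nested_elasticnet(X, y, n_iter = 5, test_n = 15, seed = 87)
  r2 <- nested_elasticnet(X, y, n_iter = 5, test_n = 15, seed = 87)
  expect_identical(r1$stability, r2$stability)
  expect_identical(r1$iterations$holdout_auc, r2$iterations$holdout_auc)
})

test_that("training-side choices ignore held-out feature values", {
  # canary: perturbing only the held-out rows' features leaves the selected
  # penalty and coefficient support unchanged
  set.seed(88)
  n <- 120
  X <- matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, paste0("f", 1:12)))
  y <- as.integer(X[, 1] + rnorm(n) > 0)
  r1 <- nested_elasticnet(X, y, n_iter = 1, test_n = 15, seed = 89)
  test_rows <- r1$iterations$test_ids[[1]]
  X2 <- X
  X2[test_rows, ] <- matrix(rnorm(length(test_rows) * ncol(X)),
                            nrow = length(test_rows))
  r2 <- nested_elasticnet(X2, y, n_iter = 1, test_n = 15, seed = 89)
  expect_identical(r1$iterations$lambda, r2$iterations$lambda)
  expect_identical(r1$iterations$alpha, r2$iterations$alpha)
  expect_identical(r1$iterations$selected, r2$iterations$selected)
  expect_false(identical(r1$iterations$holdout_auc, r2$iterations$holdout_auc))
})

test_that("stability selection applies a strict threshold", {
  run <- fake_prediction_run(c(a = 0.96, b = 0.95, c = 0.99, d = 0.10))
  sel <- stability_select(run, 0.95)
  expect_setequal(sel, c("a", "c")) # 0.95 exactly is not "over 95%"
  expect_equal(sel[1], "c") # sorted by frequency
  empty <- fake_prediction_run(c(a = 0.2, b = 0.1))
  expect_warning(out <- stability_select(empty), "no feature")
  expect_length(out, 0)
})

test_that("parsimonious evaluation produces coherent AUC and confusion counts", {
  set.seed(90)
  n <- 160
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(n, 1, plogis(2 * X[, 1]))
  ev <- evaluate_parsimonious(X, y, k_folds = 8, seed = 91)
  cm <- ev$confusion
  expect_equal(cm$TP + cm$FP + cm$TN + cm$FN, n)
  expect_equal(cm$sensitivity, cm$TP / (cm$TP + cm$FN))
  expect_equal(cm$specificity, cm$TN / (cm$TN + cm$FP))
  expect_gt(ev$auc, 0.6)
  # strongly separated subset: near-perfect pooled AUC
  y2 <- as.integer(X[, 1] > 0)
  ev2 <- suppressMessages(evaluate_parsimonious(X, y2, k_folds = 5, seed = 92))
  expect_gte(ev2$auc, 0.95)
  expect_error(evaluate_parsimonious(X, y, k_folds = 1), "k_folds")
})

test_that("nested CV and parsimonious evaluation agree on planted signal", {
  sim <- generate_cohort(generator_config(
    n_participants = 250, features_per_modality = c(GM = 40),
    outcome_n_informative = 5, outcome_auc_target = 0.85,
    signal_strength = 0, site_location_sd = 0, site_scale_sd = 0,
    covariate_effects = c(age = 0, sex = 0, motion = 0), seed = 93))
  feats <- dplyr::select(sim$features$GM, -"participant_id")
  run <- nested_elasticnet(feats, sim$cohort$remission, n_iter = 15,
                           test_n = 20, seed = 94)
  inf <- sim$truth$informative_feature_ids
  top5 <- run$stability$feature[1:5]
  expect_gte(sum(inf %in% top5), 4) # informative features dominate
  ev <- suppressMessages(evaluate_parsimonious(
    feats[, inf, drop = FALSE], sim$cohort$remission, k_folds = 8, seed = 95))
  expect_lt(abs(ev$auc - run$mean_auc), 0.08)
})

test_that("symptom-change PLS recovers exact and planted signal", {
  set.seed(96)
  n <- 100
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- 2 * X[, 1] - X[, 2] + 0.5 * X[, 3] # noise-free linear outcome
  res <- pls_madrs_change(X, y, n_components = 3, n_perm = 50, seed = 97)
  expect_equal(res$variance_explained, 1, tolerance = 1e-4)
  expect_lte(res$permutation$p_value, 0.05)
  # rows without an observed endpoint are excluded with a message
  y2 <- y; y2[1:5] <- NA
  expect_message(res2 <- pls_madrs_change(X, y2, n_components = 1,
                                          n_perm = 20, seed = 98),
                 "excluded")
  expect_equal(res2$fit$dims[["n"]], n - 5)
})

test_that("null outcomes give calibrated change-model p-values", {
  nsim <- 40
  pvals <- numeric(nsim)
  set.seed(99)
  for (i in seq_len(nsim)) {
    X <- matrix(rnorm(80 * 10), 80, 10, dimnames = list(NULL, paste0("f", 1:10)))
    y <- rnorm(80)
    pvals[i] <- pls_madrs_change(X, y, n_components = 1, n_perm = 60,
                                 seed = i)$permutation$p_value
  }
  expect_lte(mean(pvals < 0.05), 0.15)
  expect_gt(mean(pvals), 0.3) # roughly uniform, not concentrated near 0
})
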