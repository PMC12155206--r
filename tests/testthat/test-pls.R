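test_that("one-component weights equal the dominant singular vector of X'Y", {
  # independent oracle: brute-force SVD of the cross-covariance matrix
  for (i in 1:25) {
    d <- rand_xy(i)
    fit <- fit_pls(d$X, d$Y, 1, check = FALSE)
    sv <- svd(crossprod(d$X, d$Y))$u[, 1]
    cosine <- abs(sum(fit$x_weights[, 1] * sv)) /
      sqrt(sum(fit$x_weights[, 1]^2) * sum(sv^2))
    expect_gt(cosine, 0.999)
  }
})

test_that("a perfectly explained outcome yields variance explained of 1", {
  # rank-1 case: with mutually orthogonal predictors, a single component
  # reproduces an outcome equal to one predictor exactly
  set.seed(41)
  X <- qr.Q(qr(scale(matrix(rnorm(100), 20, 5))))
  X <- scale(X)
  Y <- X[, 1, drop = FALSE]
  fit <- fit_pls(X, Y, 1, check = FALSE)
  expect_equal(fit$total_variance_explained, 1, tolerance = 1e-10)
})

test_that("saturated PLS reproduces ordinary least squares", {
  set.seed(42)
  X <- scale(matrix(rnorm(40), 10, 4))
  Y <- scale(matrix(rnorm(30), 10, 3))
  fit <- fit_pls(X, Y, 4, check = FALSE)
  ols <- solve(crossprod(X), crossprod(X, Y))
  expect_equal(unname(fit$beta), unname(ols), tolerance = 1e-8)
})

test_that("scores are orthogonal and variance explained is monotone", {
  set.seed(43)
  X <- scale(matrix(rnorm(50 * 12), 50, 12))
  Y <- scale(matrix(rnorm(50 * 4), 50, 4))
  fit <- fit_pls(X, Y, 4, check = FALSE)
  g <- crossprod(fit$x_scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  expect_true(all(diff(fit$variance_explained$cumulative) >= -1e-12))
  expect_lte(fit$variance_explained$cumulative[4], 1 + 1e-12)
})

test_that("variance explained is invariant to joint row and column permutation", {
  set.seed(44)
  X <- scale(matrix(rnorm(60 * 8), 60, 8))
  Y <- scale(matrix(rnorm(60 * 3), 60, 3))
  base <- fit_pls(X, Y, 2, check = FALSE)$total_variance_explained
  for (i in 1:5) {
    rows <- sample(60); cols <- sample(8)
    perm <- fit_pls(X[rows, cols], Y[rows, ], 2, check = FALSE)
    expect_equal(perm$total_variance_explained, base, tolerance = 1e-10)
  }
})

test_that("preconditions are enforced", {
  set.seed(45)
  X <- matrix(rnorm(40), 10, 4) + 5 # not centered
  Y <- scale(matrix(rnorm(20), 10, 2))
  expect_error(fit_pls(X, Y, 1), "standardized")
  Xz <- scale(matrix(rnorm(40), 10, 4))
  expect_error(fit_pls(Xz, Y, 3), "n_components")
  expect_error(fit_pls(Xz, Y, 0, check = FALSE), "n_components")
  expect_error(permutation_test(Xz, Y, 1, n_perm = 0), "n_perm")
})

test_that("agrees with an independent regression-mode PLS implementation", {
  set.seed(46)
  X <- scale(matrix(rnorm(80 * 10), 80, 10))
  Y <- scale(matrix(rnorm(80 * 5), 80, 5))
  fit <- fit_pls(X, Y, 3, check = FALSE)
  ref <- suppressMessages(mixOmics::pls(X, Y, ncomp = 3, mode = "regression",
                                        scale = FALSE))
  for (h in 1:3) {
    expect_gt(abs(cor(fit$x_scores[, h], ref$variates$X[, h])), 0.999)
  }
})

test_that("permutation p-values are seeded, bounded, and powered", {
  sim <- generate_cohort(generator_config(
    n_participants = 200, features_per_modality = c(GM = 30),
    signal_strength = 0.3, missing_cognition_rate = 0,
    site_location_sd = 0, site_scale_sd = 0, seed = 47))
  Xz <- zscore_columns(sim$features$GM)
  Yz <- zscore_columns(sim$cognition)
  p1 <- permutation_test(Xz, Yz, 2, n_perm = 500, seed = 48)
  p2 <- permutation_test(Xz, Yz, 2, n_perm = 500, seed = 48)
  expect_identical(p1$null_distribution, p2$null_distribution)
  expect_lte(p1$p_value, 0.01) # strong planted signal
  expect_gte(p1$p_value, 1 / 501) # +1 correction lower bound
  expect_equal(length(p1$null_distribution), 500)
})

test_that("sequential component selection tracks the planted factor count", {
  count_for <- function(k_true, nsim = 50, n = 150, p = 20) {
    sapply(seq_len(nsim), function(i) {
      cfg <- generator_config(
        n_participants = n, features_per_modality = c(GM = p),
        n_latent_factors = max(k_true, 1),
        signal_strength = if (k_true == 0) 0 else 0.25,
        loading_sparsity = 0.4, factor_feature_cor = 0.6,
        site_location_sd = 0, site_scale_sd = 0,
        missing_cognition_rate = 0,
        covariate_effects = c(age = 0, sex = 0, motion = 0),
        seed = 700 * k_true + i)
      sim <- generate_cohort(cfg)
      select_n_components(zscore_columns(sim$features$GM),
                          zscore_columns(sim$cognition),
                          max_components = 3, n_perm = 200, seed = i)
    })
  }
  k0 <- count_for(0)
  expect_gte(mean(k0 == 0), 0.90) # null: nothing retained
  k1 <- count_for(1)
  expect_gte(mean(k1 == 1), 0.90) # one strong factor
  k2 <- count_for(2, n = 300)
  expect_gt(mean(k2 == 2), 0.5) # two factors, large n: majority
})

test_that("bootstrap ratios flag planted features and spare null ones", {
  sim <- generate_cohort(generator_config(
    n_participants = 200, features_per_modality = c(GM = 60),
    n_latent_factors = 1, loading_sparsity = 0.15, factor_feature_cor = 0.5,
    signal_strength = 0.15, site_location_sd = 0, site_scale_sd = 0,
    missing_cognition_rate = 0,
    covariate_effects = c(age = 0, sex = 0, motion = 0), seed = 50))
  L <- sim$truth$factor_loadings_X$GM
  planted <- rownames(L)[L[, 1] != 0]
  Xz <- zscore_columns(sim$features$GM)
  Yz <- zscore_columns(sim$cognition)
  bt <- bootstrap_loadings(Xz, Yz, 1, n_boot = 300, seed = 51)
  flagged <- rownames(bt$z_ratio)[bt$significant_mask[, 1]]
  expect_gte(sum(planted %in% flagged), length(planted) - 1)
  expect_lte(sum(!(flagged %in% planted)), 2)
  # reproducible under the same seed
  bt2 <- bootstrap_loadings(Xz, Yz, 1, n_boot = 300, seed = 51)
  expect_identical(bt$z_ratio, bt2$z_ratio)
})

test_that("null data rarely produce |Z| > 3 bootstrap ratios", {
  sim <- generate_cohort(null_config(seed = 52, n = 100, p = 150, q = 5))
  Xz <- zscore_columns(sim$features$GM)
  Yz <- zscore_columns(sim$cognition)
  bt <- bootstrap_loadings(Xz, Yz, 1, n_boot = 200, seed = 53)
  expect_lte(mean(bt$significant_mask[, 1]), 0.02)
})

test_that("duplicating every participant leaves bootstrap-ratio direction unchanged", {
  sim <- generate_cohort(generator_config(
    n_participants = 120, features_per_modality = c(GM = 25),
    n_latent_factors = 1, signal_strength = 0.25, loading_sparsity = 0.3,
    site_location_sd = 0, site_scale_sd = 0, missing_cognition_rate = 0,
    seed = 54))
  Xz <- latentcog:::as_feature_matrix(zscore_columns(sim$features$GM))
  Yz <- latentcog:::as_feature_matrix(zscore_columns(sim$cognition))
  b1 <- bootstrap_loadings(Xz, Yz, 1, n_boot = 200, seed = 55)
  b2 <- bootstrap_loadings(rbind(Xz, Xz), rbind(Yz, Yz), 1,
                           n_boot = 200, seed = 56)
  expect_gt(cor(b1$z_ratio[, 1], b2$z_ratio[, 1]), 0.8)
})

test_that("latent-test correlations apply the Bonferroni family correctly", {
  set.seed(57)
  X <- scale(matrix(rnorm(200 * 10), 200, 10))
  Y <- scale(matrix(rnorm(200 * 12), 200, 12,
                    dimnames = list(NULL, sprintf("test%02d", 1:12))))
  fit <- fit_pls(X, Y, 2, check = FALSE)
  ltc <- latent_test_correlations(fit, Y)
  expect_equal(nrow(ltc), 24) # 2 components x 12 tests
  expect_equal(ltc$p_bonferroni, pmin(ltc$p * 24, 1))
  # a test equal to a latent score is maximally significant
  Y2 <- Y; Y2[, 1] <- fit$x_scores[, 1]
  ltc2 <- latent_test_correlations(fit, Y2)
  row <- ltc2[ltc2$component == "LV1" & ltc2$test == "test01", ]
  expect_equal(row$r, 1, tolerance = 1e-12)
  expect_true(row$significant)
  # constant columns are flagged not-significant with a warning
  Y3 <- Y; Y3[, 2] <- 0
  expect_warning(ltc3 <- latent_test_correlations(fit, Y3), "constant")
  expect_false(any(ltc3$significant[ltc3$test == "test02"]))
})

test_that("covariate associations return Pearson r with two-sided p", {
  set.seed(58)
  s <- rnorm(100)
  expect_equal(association_with_covariate(s, s)$estimate, 1)
  expect_equal(association_with_covariate(s, -s)$estimate, -1)
  ind <- association_with_covariate(s, rnorm(100))
  expect_lt(abs(ind$estimate), 0.3)
  expect_error(association_with_covariate(s, rep(1, 100)), "constant")
  expect_error(association_with_covariate(s[1:3], s[1:3]), "4")
})
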