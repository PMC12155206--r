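# Two-site fixture with exactly planted location/scale effects and an
# optional covariate slope, for parameter-level checks.
planted_sites <- function(seed, n = 200, p = 20, shift = 0, scale_ratio = 1,
                          age_slope = 0) {
  set.seed(seed)
  site <- rep(c("A", "B"), each = n / 2)
  age <- rnorm(n, 68, 6)
  base <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  # site effects act on the residual (location/scale model); covariate
  # effects are added afterwards, untouched by site
  base[site == "B", ] <- base[site == "B", ] * scale_ratio + shift
  x <- base + age_slope * (age - mean(age))
  list(x = x, cohort = tibble::tibble(
    participant_id = paste0("P", 1:n), site = site, age = age,
    sex = rbinom(n, 1, 0.5)))
}

test_that("planted location shifts are removed", {
  # a shift common to every feature: empirical-Bayes shrinkage removes the
  # pooled shift exactly, leaving only per-feature sampling noise
  d <- planted_sites(1, n = 400, shift = 2)
  out <- as.matrix(harmonize(d$x, d$cohort, c("age", "sex")))
  diffs <- colMeans(out[d$cohort$site == "A", ]) -
    colMeans(out[d$cohort$site == "B", ])
  expect_lt(mean(abs(diffs)), 0.1)
  expect_lt(max(abs(diffs)), 0.2)
  # feature-specific shifts: near-exact per-feature removal
  set.seed(99)
  d2 <- planted_sites(3, n = 400)
  shifts <- rnorm(ncol(d2$x), 0, 1)
  d2$x[d2$cohort$site == "B", ] <-
    sweep(d2$x[d2$cohort$site == "B", ], 2, shifts, "+")
  out2 <- as.matrix(harmonize(d2$x, d2$cohort, c("age", "sex")))
  diffs2 <- colMeans(out2[d2$cohort$site == "A", ]) -
    colMeans(out2[d2$cohort$site == "B", ])
  expect_lt(max(abs(diffs2)), 0.1)
})

test_that("planted scale ratios are equalized", {
  d <- planted_sites(2, n = 400, scale_ratio = 2)
  out <- as.matrix(harmonize(d$x, d$cohort, c("age", "sex")))
  ratio <- apply(out[d$cohort$site == "A", ], 2, var) /
    apply(out[d$cohort$site == "B", ], 2, var)
  expect_true(all(ratio > 0.8 & ratio < 1.25))
})

test_that("data without site effects pass through nearly unchanged", {
  d <- planted_sites(3)
  out <- as.matrix(harmonize(d$x, d$cohort, c("age", "sex")))
  cors <- vapply(seq_len(ncol(out)), function(j) cor(out[, j], d$x[, j]),
                 numeric(1))
  expect_true(all(cors > 0.99))
})

test_that("protected covariate slopes survive harmonization", {
  d <- planted_sites(4, n = 400, shift = 1.5, scale_ratio = 1.5,
                     age_slope = 0.5)
  out <- as.matrix(harmonize(d$x, d$cohort, c("age", "sex")))
  slopes <- vapply(seq_len(ncol(out)), function(j)
    coef(lm(out[, j] ~ d$cohort$age))[2], numeric(1))
  expect_lt(max(abs(slopes - 0.5)), 0.05)
})

test_that("covariates can be residualized out on request", {
  d <- planted_sites(5, n = 400, age_slope = 0.5)
  out <- as.matrix(harmonize(d$x, d$cohort, c("age", "sex"),
                             remove_covariates = TRUE))
  slopes <- vapply(seq_len(ncol(out)), function(j)
    coef(lm(out[, j] ~ d$cohort$age))[2], numeric(1))
  expect_lt(max(abs(slopes)), 0.05)
})

test_that("fit/apply separation is consistent and leakage-safe", {
  d <- planted_sites(6, n = 300, shift = 1, scale_ratio = 1.3)
  model <- fit_harmonization(d$x, d$cohort, c("age", "sex"))
  # applying the model to its own training data equals the one-shot output
  expect_equal(as.matrix(apply_harmonization(model, d$x, d$cohort)),
               as.matrix(harmonize(d$x, d$cohort, c("age", "sex"))))
  # held-out participants from seen sites are adjusted deterministically
  test_rows <- 1:20
  a <- apply_harmonization(model, d$x[test_rows, ], d$cohort[test_rows, ])
  b <- apply_harmonization(model, d$x[test_rows, ], d$cohort[test_rows, ])
  expect_identical(a, b)
  # unseen site labels are an error
  bad <- d$cohort[test_rows, ]; bad$site <- "C"
  expect_error(apply_harmonization(model, d$x[test_rows, ], bad), "not seen")
})

test_that("matches the reference parametric empirical-Bayes adjustment", {
  sim <- tiny_sim(seed = 7, n = 160, gm = 25)
  X <- latentcog:::as_feature_matrix(sim$features$GM)
  mine <- latentcog:::as_feature_matrix(
    harmonize(sim$features$GM, sim$cohort, c("age", "sex")))
  ref <- t(suppressMessages(sva::ComBat(
    dat = t(X), batch = sim$cohort$site,
    mod = stats::model.matrix(~ age + sex, sim$cohort))))
  expect_lt(max(abs(mine - ref)), 1e-8)
})

test_that("empirical-Bayes shrinkage pulls small-site estimates toward the prior", {
  set.seed(8)
  n_small <- 6; n_big <- 200; p <- 40
  site <- c(rep("small", n_small), rep("big", n_big))
  x <- matrix(rnorm((n_small + n_big) * p), ncol = p,
              dimnames = list(NULL, paste0("f", 1:p)))
  cohort <- tibble::tibble(participant_id = seq_along(site), site = site,
                           age = rnorm(length(site), 68, 6))
  m <- fit_harmonization(x, cohort, "age")
  raw <- m$gamma_hat["small", ]
  post <- m$gamma_star["small", ]
  prior <- mean(raw)
  # posterior strictly between the raw estimate and the prior mean
  moved <- abs(post - prior) < abs(raw - prior)
  expect_true(mean(moved) > 0.95)
})

test_that("degenerate inputs are handled explicitly", {
  d <- planted_sites(9, n = 40, p = 5)
  one_site <- d$cohort; one_site$site <- "A"
  expect_warning(m <- fit_harmonization(d$x, one_site, "age"), "single site")
  expect_equal(as.matrix(apply_harmonization(m, d$x, one_site)),
               d$x, tolerance = 1e-12)
  lone <- d$cohort; lone$site[1] <- "C"
  expect_error(fit_harmonization(d$x, lone, "age"), "single participant")
  # zero within-site variance features are passed through with a warning
  x2 <- d$x; x2[, 1] <- 5
  expect_warning(out <- harmonize(x2, d$cohort, "age"), "zero within-site")
  expect_equal(out[[1]], x2[, 1])
})

test_that("site-effect removal does not distort brain-cognition signal", {
  sim <- generate_cohort(generator_config(
    n_participants = 400, features_per_modality = c(GM = 40),
    signal_strength = 0.15, site_location_sd = 1, site_scale_sd = 0.35,
    missing_cognition_rate = 0, seed = 10))
  Y <- as.matrix(sim$cognition[-1])
  obs <- latentcog:::as_feature_matrix(sim$features$GM)
  # reconstruct the site-effect-free features from the ground truth
  si <- match(sim$cohort$site, rownames(sim$truth$site_location$GM))
  clean <- (obs - sim$truth$site_location$GM[si, ]) /
    sim$truth$site_scale$GM[si, ]
  harm <- latentcog:::as_feature_matrix(
    harmonize(sim$features$GM, sim$cohort, c("age", "sex")))
  L <- sim$truth$factor_loadings_X$GM
  loaded <- which(rowSums(L != 0) > 0)
  drift <- vapply(loaded, function(f) {
    k <- which(L[f, ] != 0)[1]
    tests <- which(sim$truth$factor_loadings_Y[, k] != 0)
    mean(abs(cor(harm[, f], Y[, tests]) - cor(clean[, f], Y[, tests])))
  }, numeric(1))
  expect_lt(mean(drift), 0.05)
})
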