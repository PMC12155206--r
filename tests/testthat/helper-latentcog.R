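# Shared fixture builders. Everything is generated in code under fixed
# seeds; no stored data.

# A small cohort with modest feature counts, fast enough for unit tests.
tiny_sim <- function(seed = 1, n = 120, gm = 30, fc = 45, wm = 20, ...) {
  generate_cohort(generator_config(
    n_participants = n,
    features_per_modality = c(FC = fc, WM = wm, GM = gm),
    seed = seed, ...))
}

# Signal-free generator settings (no site effects, no covariates, no
# missingness) for null simulations.
null_config <- function(seed, n = 100, p = 30, q = 12) {
  generator_config(
    n_participants = n, features_per_modality = c(GM = p),
    n_cognitive_tests = q, signal_strength = 0,
    site_location_sd = 0, site_scale_sd = 0, missing_cognition_rate = 0,
    covariate_effects = c(age = 0, sex = 0, motion = 0), seed = seed)
}

# Standardized random matrices for PLS-level tests.
rand_xy <- function(seed, n = 20, p = 5, q = 2) {
  set.seed(seed)
  list(X = scale(matrix(rnorm(n * p), n, p)),
       Y = scale(matrix(rnorm(n * q), n, q)))
}

# Evaluate expr under a local seed without disturbing the test RNG stream.
with_seed_test <- function(seed, expr) latentcog:::with_seed(seed, expr)

# A minimal prediction_run skeleton for boundary tests on stability_select.
fake_prediction_run <- function(frequencies) {
  structure(list(
    stability = tibble::tibble(feature = names(frequencies),
                               frequency = unname(frequencies)),
    n_iter = 100L
  ), class = "prediction_run")
}
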