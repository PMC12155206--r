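# latentcog

Latent-variable brain–cognition analysis and treatment-outcome prediction
for multi-site cohorts.

## The problem

Multi-site neuroimaging studies of late-life treatment-resistant depression
relate three brain feature blocks — functional connectivity (pairwise edges
among resting-state network components), white-matter tract integrity
(fractional anisotropy per tract), and gray-matter structure (cortical
thickness and subcortical volumes) — to a 12-test cognitive battery
spanning six domains, and ask whether those same markers predict remission
(MADRS ≤ 10) under antidepressant treatment. Doing this credibly requires a
chain of steps, each of which this package implements as a tested, reusable
function:

- **QC filters** with the field's boundary conventions: keep mean framewise
  displacement strictly below 0.7 mm, exclude surface-hole counts strictly
  above 380, drop tracts with more than 3% unusable data, mean-impute
  sparse cognitive missingness, and score white-matter hyperintensity
  burden as `sqrt(WMH volume / ICV)`.
- **Site harmonization**: parametric empirical-Bayes location/scale batch
  adjustment that removes site effects while protecting age, sex, and (for
  functional connectivity) mean head motion — with fit/apply separation so
  a model trained on one sample can be applied leakage-free to held-out
  participants.
- **PLS regression** (NIPALS, regression mode): latent variables that
  maximize the cross-block covariance between z-scored brain features X
  and cognition Y. Model significance by permutation of Y's rows
  (p = (1 + #{null ≥ observed}) / (n_perm + 1)); per-feature robustness by
  bootstrap ratios Z = bootstrap mean / bootstrap SE of each loading, with
  |Z| > 3 flagging robust contributors; latent-score–test correlations
  Bonferroni-corrected over the (components × tests) family.
- **Leave-one-site-out generalizability**: train on all-but-one site,
  push the held-out site's features through the training beta coefficients,
  and correlate predicted with observed composite cognition (first
  principal component of the training-significant tests).
- **Remission prediction**: 100 iterations of nested cross-validated
  elastic-net logistic regression (20 held-out participants per iteration,
  stratified; 10-fold inner CV over a mixing × shrinkage grid), stability
  selection of predictors surviving regularization in over 95% of
  iterations, and k-fold evaluation of the parsimonious model with
  confusion matrices; plus a PLS model of continuous MADRS change.
- **A synthetic multi-site cohort generator** with known ground truth
  (shared latent factors, site batch effects, covariate effects, a
  calibrated logistic outcome), so every stage is testable by parameter
  recovery.

## The model in brief

Cognition and brain features share latent factors F:

    Y = F L_y' + E_y        X = F L_x' + E_x

PLS estimates paired directions w (features) and q (tests) maximizing
cov(Xw, Y q); per component the weight vector is the dominant direction of
the X'Y cross-covariance, X is deflated by its rank-one loading term, and
the X→Y coefficient matrix B = W(P'W)⁻¹Q' maps standardized features to
predicted cognition. Site effects follow the location/scale model
x = α + covariates·β + γ_site + δ_site·ε, removed by empirical-Bayes
shrinkage of per-site, per-feature location and scale estimates toward
pooled priors.

## Worked example

Generate a four-site cohort of 230 participants, run QC, harmonize the
gray-matter block, and fit the brain–cognition model:

```r
library(latentcog)

sim <- generate_cohort(generator_config(n_participants = 230, seed = 17))
cohort <- filter_by_motion(sim$cohort) |> filter_by_surface_holes()
#> motion filter (FD < 0.7): excluded 4 participant(s).
#> surface-hole filter (> 380 excluded): 3 participant(s).

keep <- cohort$participant_id
cognition <- impute_cognition_mean(
  dplyr::filter(sim$cognition, participant_id %in% keep))
gm <- dplyr::filter(sim$features$GM, participant_id %in% keep) |>
  harmonize(cohort, covariates = c("age", "sex"))

Xz <- zscore_columns(gm); Yz <- zscore_columns(cognition)
k <- select_n_components(Xz, Yz, max_components = 3, n_perm = 500, seed = 17)
fit <- fit_pls(Xz, Yz, n_components = k)
fit
#> <pls_fit> 2 latent variable(s), n=223, p=74, q=12
#>   Y-variance explained: 9.8% (per component: 5.2%, 4.7%)

permutation_test(Xz, Yz, n_components = k, n_perm = 1000, seed = 18)
#> <pls_permutation> observed varexp = 0.0984, p = 0.000999 (n_perm = 1000)

bootstrap_loadings(Xz, Yz, n_components = k, n_boot = 1000, seed = 19)
#> <pls_bootstrap> n_boot = 1000, |Z| > 3
#>   robust features per component: 13, 13

leave_one_site_out(gm, cognition, cohort$site, n_components = k, seed = 20)
#> <loso_result>
#> # A tibble: 4 × 6
#>   site   n_test n_components n_tests_selected     r          p
#> 1 site01     55            2                9 0.473 0.000263
#> 2 site02     57            2               10 0.581 0.00000215
#> 3 site03     55            2               10 0.574 0.00000466
#> 4 site04     56            2               12 0.566 0.00000539
#>   mean held-out r = 0.549
```

Reading the output: the sequential permutation rule retained two latent
variables which together explain 9.8% of cognitive-test variance — far more
than row-permuted nulls (p ≈ 0.001). Thirteen gray-matter features load
robustly (|Z| > 3) on each latent variable, and the model generalizes
across held-out sites (predicted-vs-observed composite cognition r ≈ 0.55
per site). Results are tibble-friendly throughout: `tidy()`, `glance()`,
`autoplot()` and `plot_stability()` work on every fitted object.

The whole chain — generation/ingestion, QC, harmonization, three PLS
models, LOSO, and outcome prediction — runs from one call:

```r
res <- run_pipeline(pipeline_config(
  generator = generator_config(n_participants = 230, seed = 0),
  n_perm = 1000, n_boot = 1000, n_iter = 50,
  seed = 42, output_dir = "run1"))
```

which writes every intermediate table as CSV plus `manifest.json` and a
human-readable `report.txt`; reruns with the same config and seed are
byte-identical.

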