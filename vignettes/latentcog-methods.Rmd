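---
title: "Methods: latent-variable brain-cognition modelling in multi-site cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent-variable brain-cognition modelling in multi-site cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its statistical machinery: the
models and their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, the numerical choices, and the design decisions taken where more
than one defensible reading existed.

## The scientific setting

The package targets multi-site observational/trial cohorts of older adults
with treatment-resistant depression, where three brain feature blocks are
measured per participant — functional connectivity (FC; pairwise edges
among resting-state network components, e.g. 210 edges among 21
components), white-matter tract fractional anisotropy (WM; ~62 tracts
after quality filtering), and gray-matter structure (GM; ~74 cortical
thickness and subcortical volume variables) — alongside a 12-test
cognitive battery covering attention, immediate and delayed memory,
language, visuospatial and executive function, clinical scores (baseline
MADRS, treatment-resistance history, medical burden), and QC covariates
(head motion, intracranial volume, surface quality).

Three questions structure the pipeline: (1) which latent combinations of
brain features covary with cognition, and are they statistically solid;
(2) do those latent relationships transfer to sites never seen in
training; (3) do baseline features predict remission under treatment.

## Quality control and transforms

Boundary semantics are taken literally from standard usage and implemented
strictly: participants are *kept* when mean framewise displacement is
strictly below the threshold (default 0.7 mm; 0.5 mm as a sensitivity
setting), *excluded* when surface-hole counts are strictly above 380, and
tracts are dropped when strictly more than 3% of their data is unusable
(a tract at exactly 3% stays). Missing cognitive scores are replaced by
the observed per-test mean — defensible because per-test missingness in
this setting is low (3–5%) and assumed completely at random; the
missingness mask is kept on the result for audit. White-matter
hyperintensity volume is expressed as `sqrt(WMH / ICV)` to de-skew.

Whether cognition is imputed before or after MRI-based exclusions is not
fixed by the pipeline: both orders work, because the imputation function
computes means over whatever sample it receives. `run_pipeline()` imputes
after the participant-level filters, i.e. over the analysis sample.

Z-scoring returns its means and SDs so held-out data are always
standardized with *training* parameters; a zero-variance column is an
error naming the column rather than a silent zero.

## Site harmonization

The harmonizer implements the parametric empirical-Bayes location/scale
batch model: per feature g and site s,

$$x_{isg} = \alpha_g + \mathbf{c}_i^\top \beta_g + \gamma_{sg} + \delta_{sg}\,\varepsilon_{isg},$$

fitted by per-feature least squares with site indicators plus protected
covariates, standardized by the pooled residual variance, with per-site
location (normal prior) and scale (inverse-gamma prior) estimates shrunk
toward pooled priors by iterated conditional posterior means (relative
tolerance 1e-4, capped at 100 iterations). The parametric variant was
chosen because it is the standard one and has closed-form updates; the
nonparametric variant is out of scope.

Covariates are **protected** by default: age, sex (and mean head motion
for FC, which is motion-sensitive by construction) are re-added after
batch adjustment. The alternative reading — residualize covariates too —
is available via `remove_covariates = TRUE`. GM harmonization is off by
default in the pipeline (`harmonize_gm = FALSE`), reflecting that batch
normalization is most critical for the FC and diffusion blocks; it can be
switched on.

Two deliberate consequences of empirical Bayes are worth knowing. First,
a fitted model separates cleanly into fit and apply steps, so held-out
participants from *seen* sites can be adjusted without refitting (unseen
site labels are an error). Second, shrinkage means per-feature site means
are not forced exactly to equality: when planted site shifts are
homogeneous across features, the posterior removes the pooled shift and
leaves each feature's sampling deviation in place. Site-effect removal
should therefore be assessed through covariate-adjusted site coefficients,
not raw site means — raw means also carry legitimate differences in
covariate composition between sites. Features with zero within-site
variance anywhere are excluded from the empirical-Bayes step and passed
through unchanged, with a warning.

## PLS engine

`fit_pls()` implements NIPALS regression-mode PLS: per component the
weight vector is the dominant direction of the current cross-covariance
$S = X_d^\top Y$, scores $t = X_d w$, loadings $p = X_d^\top t / t^\top t$
and $q = Y^\top t / t^\top t$, then $X_d \leftarrow X_d - t p^\top$ (X
deflation only; Y is not deflated). The dominant direction is computed
exactly from the small $q \times q$ Gram matrix $S^\top S$ — the NIPALS
fixed point — rather than by iterated power steps, which converge slowly
precisely when the leading singular values are close (i.e. on the
near-null data that permutation tests spend most of their time on).
Regression-mode NIPALS was chosen over SIMPLS; the two coincide for one
component and differ negligibly beyond it. The sign convention (largest
absolute weight element positive per component) makes fits deterministic.
The coefficient matrix $B = W (P^\top W)^{-1} Q^\top$ maps standardized X
to predicted standardized Y; in the saturated limit it reproduces
ordinary least squares, which the tests verify.

**Permutation test.** The model-level statistic is the total fraction of
Y-variance explained by the retained components; rows of Y are permuted,
the model refitted, and $p = (1 + \#\{\text{null} \ge \text{obs}\}) /
(n_{perm} + 1)$ — conservative by construction, with p-values
stochastically at least uniform under the null. The study-scale default is
5000 permutations; calibration tests run at 200.

**Component count.** The per-modality component count is chosen by a
sequential permutation rule: retain a component only while the leading
component of the current (deflated X, residualized Y) pair beats its
permutation null at level alpha. This is a defensible rule, not a claim
about how any particular published count was chosen; a fixed integer can
be passed instead.

**Bootstrap ratios.** Participants are resampled with replacement,
re-standardized, refitted; each replicate's components are aligned to the
original fit by maximal absolute correlation between replicate-projected
and original scores (order, then sign) — without alignment, sign and
order indeterminacy would destroy the ratios. The bootstrap ratio is the
bootstrap mean over the bootstrap SE of each X-loading, and |Z| > 3 flags
robust features. The mean/SE convention is the bootstrap-ratio convention
of the PLS neuroimaging literature; the original-loading/SE alternative
changes little in practice.

**Follow-up associations.** Latent-score–test correlations are
Bonferroni-corrected within one modality model over the (components ×
tests) family — e.g. 24 comparisons for a 2-component model over 12
tests. Covariate follow-ups (education, brain-structure centile,
treatment-resistance history, WMH burden) are plain Pearson correlations
with two-sided p-values.

**Debiased variance explained.** In-sample variance explained is
upward-biased (null data still yield a positive maximum-covariance
component; roughly 2–3% at p = 30, n = 250 with two components).
`variance_explained_debiased()` subtracts the mean of the permutation
null; this estimator recovers planted signal fractions of 0.05–0.15
within ±0.03 in the package's recovery tests.

## Generalizability (leave-one-site-out)

For each held-out site: standardize training X and Y, fit the PLS model,
select the cognitive tests significantly associated with the training
latent scores (Bonferroni), build the first-principal-component composite
of those tests on training data (sign fixed to correlate positively with
their mean), then standardize the held-out site with training scalers,
predict its cognition through the training coefficient matrix, and
correlate predicted with observed composite scores. Test selection happens
*inside* each training fold — the leakage-free reading; a fixed test list
reproduces the alternative. The composite weights are applied to the
predicted Y columns; correlations are invariant to the affine maps
involved, so composite construction order does not change the result.
Sites smaller than 3 are skipped with a warning. A leakage audit is part
of the test suite: replacing the held-out site's cognition with noise
leaves every training artifact byte-identical.

## Outcome prediction

Remission is predicted by iterated nested cross-validated elastic-net
logistic regression: on each of 100 iterations (default), 20 participants
are held out — stratified by outcome, since unstratified 20-participant
draws would occasionally be single-class and leave AUC undefined — and the
penalty is chosen inside the training split by stratified 10-fold CV over
a grid of mixing parameters {0.1, 0.5, 0.9} × 20 log-spaced shrinkage
values (the grid is a package choice; no canonical grid exists).
"Surviving regularization" is read as a nonzero coefficient at the
inner-CV-selected penalty; a feature is *stable* when that happens in
strictly more than 95% of iterations (96/100 qualifies, 95/100 does not).
The parsimonious model — unpenalized logistic regression on the stable
set, with a lightly ridge-stabilized fallback under quasi-separation — is
evaluated by stratified k-fold CV (8-fold and 5-fold in the two treatment
steps of the motivating design), pooling out-of-fold probabilities into
one AUC and a confusion matrix at the 0.5 probability threshold (a
Youden-optimal threshold is available, since a published
sensitivity/specificity pair implies an operating point the package
cannot know). AUC is the Mann-Whitney rank statistic with midrank tie
correction, so a constant probability scores exactly 0.5. Distinct
treatment steps should be run as separate datasets. Continuous MADRS
change is modelled by single-outcome PLS with a permutation p and a
random-split hold-out correlation.

Two reading notes. First, at ~90 predictors and n ≈ 200 the permutation
test of the change model has modest power: the null distribution of a
single maximum-covariance component is itself large, so a real signal can
show a clear hold-out correlation while the in-sample permutation p stays
unremarkable. Second, rows without an observed endpoint are excluded with
a logged count; baseline severity is penalized like any other predictor
by default.

## The synthetic-data generator

`generate_cohort()` draws shared factor scores F and builds
$Y = F L_y^\top + E_y$, $X = F L_x^\top + E_x$: each factor loads on a
sparse subset of features per modality (default 20%, at feature-factor
correlation 0.5) and on a disjoint block of tests, with the nonzero test
loadings set to $\sqrt{s}$ and noise variance $1-s$ so the factors explain
exactly the configured `signal_strength` of cognition variance in the
population. Site effects follow the same additive-location /
multiplicative-scale model the harmonizer assumes (defaults: location SD
0.4, log-scale SD 0.2 — visible but realistic batch effects); covariate
effects add age, sex and motion slopes; cognitive scores are deleted
completely at random at rate 0.04 (the low-missingness regime that
justifies mean imputation). Remission labels are drawn from a logistic
model on a sparse gray-matter subset whose slope is calibrated by
quadrature so the true linear predictor discriminates at
`outcome_auc_target` (default 0.75) at a target prevalence of 0.45;
continuous symptom change shares the same informative features at a
configurable planted R² (default 0.3). Demographic marginals (age
N(68, 6), ~68% one sex, baseline MADRS 20–45) mimic a late-life
treatment-resistant depression sample for realism only.

Default cohort scale is 230 participants across 4 approximately balanced
sites with FC = 210, WM = 62, GM = 74 features and 12 tests — the scale of
a multi-site imaging substudy.

What the generator does **not** emulate: geometric structure in
connectomes (edges are exchangeable), spatial autocorrelation among
features, site-by-covariate interactions, longitudinal visits, informative
dropout, and non-MCAR missingness. Passing recovery tests therefore shows
the estimators are correct under the stated model, not that real data meet
that model.

## Numerical choices and test scales

- All randomized procedures take explicit seeds; the pipeline derives
  per-stage seeds from one master seed via a deterministic stage-label
  hash, so stages are independently reproducible.
- Empirical-Bayes iteration: relative tolerance 1e-4, cap 100 iterations
  (the cap is never reached in practice); the implementation matches the
  reference parametric adjustment to ~1e-14 on shared inputs.
- Degenerate bootstrap resamples (a zero-variance column) are redrawn with
  a bounded retry budget; degenerate single-class label draws likewise.
- Recovery and calibration tests run at deliberately modest scales chosen
  to keep the whole suite fast while leaving clear margins: permutation
  calibration on 500 null datasets (n = 100, p = 30, q = 12, 200
  permutations), bootstrap recovery at n = 200 with 500 resamples,
  variance-explained recovery on 50 simulations per signal level at
  n = 250 with half the features loading at correlation 0.7 (so
  measurement attenuation stays negligible relative to the ±0.03 band),
  stability selection at n = 400 with 100 iterations, and the end-to-end
  determinism check at n = 200 with 200 permutations/resamples and 25
  iterations.

## Known limitations

- Harmonization assumes additive/multiplicative site effects on otherwise
  comparable feature distributions; it cannot fix site-confounded biology
  (e.g. one site enrolling systematically sicker patients) and protected
  covariates must be measured without site-dependent bias.
- The sequential permutation rule for component count controls each step
  at level alpha but is not a global error rate.
- Stability selection frequencies depend on the penalty grid; the >95%
  threshold is a convention, and near-threshold features can enter or
  leave the parsimonious set as the iteration count grows.
- The generator's exchangeable features make bootstrap false-flag rates
  slightly optimistic relative to spatially correlated real features.
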