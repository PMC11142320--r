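---
title: "Multilevel functional analysis of postprandial CGM curves: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel functional analysis of postprandial CGM curves: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmfda)
```

## The problem

Continuous glucose monitors record interstitial glucose every five minutes.
After a meal, the resulting trajectory over the following hours carries far
more information than the scalar summaries (2-hour AUC, peak glucose)
usually extracted from it. `cgmfda` treats the six-hour post-dinner
trajectory `Y_ij(t)`, `t ∈ [0, 360]` minutes, of subject `i` at meal `j` as
a functional observation, and provides the full analysis chain: window
extraction with quality filters, a two-level functional principal component
decomposition, function-on-scalar regression with subject-specific
random-effect functions, and a pointwise/global R² for hierarchical
functional models.

Because repeated meals from the same person are correlated, every model in
the package is explicitly hierarchical: variation is split into a
between-subject level (a subject's habitual response shape) and a
within-subject, meal-to-meal level.

## Models

### Two-level decomposition (MFPCA)

The decomposition model is

    Y_ij(t) = mu(t) + nu_j(t) + U_i(t) + W_ij(t) + e_ij(t),

with a smooth global mean `mu`, optional meal-ordinal shifts `nu_j`
constrained to sum to zero (off by default: there is no reason to expect a
systematic day-specific shift in free-living dinners), a zero-mean
subject-level process `U_i` and a zero-mean meal-level process `W_ij`, plus
white measurement noise. Each process is expanded in orthonormal
eigenfunctions, `U_i = Σ_k a_ik φ_k`, `W_ij = Σ_h b_ijh ψ_h`, with Gaussian
scores whose variances are the eigenvalues `λ_k`, `γ_h`.

Estimation is deliberately transparent method-of-moments:

* `mu` is a penalized-spline smooth (REML) of the cross-sectional mean.
* The total covariance comes from same-curve residual cross-products; the
  between-subject covariance from within-subject, different-meal
  cross-products with the correct pair counts `Σ_i J_i (J_i − 1)`
  (subjects with a single meal contribute to the total surface only).
* Both raw surfaces are smoothed with tensor-product penalized splines
  (REML smoothness selection). The total surface is smoothed leaving the
  diagonal out, so the white-noise nugget stays on the raw diagonal:
  `σ²` is estimated as the average positive excess of the raw diagonal
  over the smoothed one, floored at zero.
* Eigenfunctions come from the trapezoidal-quadrature-weighted
  eigenproblem. Negative eigenvalues are truncated to zero. Signs are
  fixed by making the grid point of largest absolute value positive —
  an arbitrary but reproducible convention.
* Scores are best linear unbiased predictors under joint normality,
  solving each subject's stacked linear system for the subject- and
  meal-level scores jointly; a quadrature-projection estimator is
  available as an option. The BLUP shrinks towards zero as noise grows,
  the projection does not. Components with (numerically) zero eigenvalue
  receive zero scores, the shrinkage limit. A singular system receives a
  1e-8 ridge jitter with a warning.

The default truncation is `K = H = 3` components per level; the
`select_components_by_r2()` table is the data-driven alternative, and in
our synthetic experiments it plateaus exactly at the generative rank.

The subject-level variance share is defined from eigenvalue sums,
`Σλ / (Σλ + Σγ)`, i.e. relative to the variance captured by the fitted
model at its truncation, not to full covariance traces — the two
definitions were both defensible and the eigenvalue-sum form is the one
that is well-defined for every truncation.

### Function-on-scalar regression (FoSR)

The regression model is

    Y_ij(t) = Σ_l X_ij,l β_l(t) + α_i(t) + ε_ij(t),

with scalar covariates `X` (meal composition, demographics, the pre-meal
glucose at −5 minutes), coefficient functions `β_l`, and a subject
random-effect function `α_i` — a random intercept function only, matching
the model; random functional slopes are out of scope. Predictors are not
standardized: coefficients stay on their natural scales (mg/dL per gram,
per year, ...).

Estimation is the scalable two-step ("pointwise-then-smooth") approach:

1. At every grid point, a linear mixed model with a random intercept per
   subject is fitted by REML (`lme4`). If the random-effect variance
   collapses to the boundary at some `t`, the fit there degenerates to
   ordinary least squares and the point is recorded.
2. Coefficient curves are smoothed across `t` with penalized splines
   (REML). The pointwise variance curve is smoothed on the same basis and
   reported as the squared standard error of the smoothed coefficient.
   This is mildly conservative for the smoothed estimator (smoothing
   reduces variance but the raw-variance curve is carried forward);
   empirically the pointwise 95% intervals cover the true coefficient
   functions at roughly 0.95–0.99 average rates in the package's
   recovery simulations.
3. Per-subject pointwise predictions are smoothed (cubic smoothing
   splines) and centered so that `Σ_i α̂_i(t) = 0` exactly at every `t`.

Pointwise correlation of `ε` across `t` is not modeled — the pointwise fits
are valid marginally per `t` — but it is respected in band construction by
resampling whole subjects.

### Joint confidence bands

Pointwise bands are `β̂ ± z·se`. Simultaneous bands rescale the same
standard-error curve by a multiplier estimated from a subject-level
(cluster) bootstrap of the maximum standardized deviation
`max_t |β*_l(t) − β̂_l(t)| / se_l(t)` over `B` resamples (default 1000,
seeded). Refitting the full REML machinery inside the bootstrap would be
needlessly expensive; resampled coefficients are computed by pointwise
generalized least squares with the variance components frozen at their
REML estimates, which is the same estimator to first order. The multiplier
is floored at the pointwise normal quantile, so the joint band contains the
pointwise band by construction. In null-effect simulations the joint band
covers the zero function in at least 95% of replicates; the bands err on
the conservative side.

### Functional R²

For fitted curves `Ỹ_ij(t)`, the pointwise R² is the standard univariate
coefficient of determination computed across all `(i, j)` curves at each
`t`; with unequal meal counts the sums simply run over all observed pairs.
It is deliberately not floored at zero — a predictor worse than the
cross-curve mean shows up as negative. Grid points where all observed
values coincide have an undefined R²; they are flagged `NA` and excluded
from the global summary with renormalized weights. The global R² is the
trapezoid-rule average `(1/360) Σ_t w(t) R²(t)`, exact for piecewise-linear
curves. All R² variants are in-sample, computed from the fitted
trajectories of the model under assessment: decomposition fits at
participant level (subject-level expansion only) and full level, and
regression fits in marginal (fixed effects only) and conditional
(plus `α̂_i`) form.

## The synthetic-data generator

No public postprandial CGM cohort with meal logs is available at the scale
the models need, so the package ships a generator that reproduces exactly
the statistical structure the models assume, making every estimation stage
testable by parameter recovery.

* **Eigenfunctions.** Closed forms for real postprandial eigenfunctions do
  not exist; the built-in library mimics the qualitative shapes seen in
  CGM studies — a nearly level first mode with a shallow concavity around
  100 minutes (overall response level), a peaked second mode at 60–80
  minutes (peak height), and an early-vs-late timing contrast — and is
  orthonormalized numerically by Gram–Schmidt under trapezoidal
  quadrature. Shapes are configurable.
* **Variance calibration.** The default splits process variance 33:67
  between the subject and meal levels, the hierarchical split reported for
  free-living post-dinner CGM. The total integrated process variance is
  144000 (mg/dL)²·min over the 360-minute window, i.e. about 20 mg/dL of
  pointwise process standard deviation, realistic for dinner responses in
  a population without diabetes; within each level the three eigenvalues
  decay as 60/30/10%.
* **Noise.** Sensor error is only loosely characterized in public sources
  (MARD near 12%); the default `noise_sd = 2` mg/dL is a modeling choice,
  small relative to the ~20 mg/dL process scale so that recovery tests
  stay sharp.
* **Day effects** default to zero under a sum-to-zero constraint.
* **Random-effect functions** `α_i(t)` are squared-exponential Gaussian
  processes with a 60-minute length-scale and 10 mg/dL marginal sd — any
  smooth zero-mean process satisfies the model's assumptions; this choice
  gives visually plausible subject offsets.
* **Covariates** are drawn independently from marginals matching a
  middle-aged European dinner cohort (carbohydrates 59.9 ± 40.5 g, fats
  30.1 ± 23.8 g, proteins 27.5 ± 17.9 g, fiber 8.8 ± 6.7 g, age 46 ± 14
  years); joint dependence between nutrients is deliberately not modeled,
  as only marginals are publicly reported.
* **Seeding.** One root seed, with deterministic per-component
  substreams: subject-level draws never change when meals are added.

What the generator does *not* emulate: circadian baselines, activity
effects, sensor drift, irregular sampling, or any physiologic (differential
equation) glucose dynamics. Passing recovery tests therefore demonstrates
correctness of the estimators under the models' own assumptions, not
robustness to the full messiness of real CGM data.

## Preprocessing rules

Raw streams are filtered per subject: the first calendar midnight-to-
midnight day of wear is discarded (sensor accuracy is worst on day one),
and any later day containing a missing run strictly longer than 120
minutes is removed entirely. The 120-minute boundary is kept (the rule is
"more than two hours"). A finger-stick calibration-count filter is exposed
only as an optional per-day predicate hook, off by default — synthetic
streams have no calibration channel. Because first-day removal is not an
idempotent operation on bare data, the filtered stream carries a marker
attribute and re-filtering is a no-op.

Windows are sampled at meal time plus grid offsets, taking the nearest
observation within ±2.5 minutes (half the cadence), ties broken toward the
later, post-meal sample. A window is kept iff at least 80% of grid points
are observed and no missing run exceeds 30 minutes; interior gaps up to 30
minutes are linearly interpolated, edge runs up to 30 minutes are filled
by nearest-value extension (linear interpolation being undefined there).
These thresholds mirror the conservative gap philosophy of the day-level
filter; they are choices, not estimates. Meals closer together than the
window length produce overlapping windows; they are retained and flagged
rather than dropped, a decision worth revisiting in sensitivity analyses.
The within-subject meal ordinal is assigned chronologically and doubles as
the day-effect index.

## Numerical choices and degenerate inputs

* Trapezoidal quadrature everywhere an integral is needed (inner
  products, eigenproblems, global R²).
* Covariance surfaces are symmetrized before and after smoothing;
  eigenvalues are floored at zero.
* A constant input curve short-circuits the penalized-spline smoother
  (no basis is needed to represent it).
* Degenerate designs fail fast: rank-deficient design matrices, a single
  subject, strata selecting no rows, and truncations exceeding the grid
  size are all rejected with messages; fits with fewer than ten subjects
  warn that bands are unreliable.
* Text serialization uses 12 significant digits, enough to make re-runs
  byte-identical while keeping files readable.

## Problem sizes used in the shipped checks

The package's recovery checks run at the generator's default study
conditions — n = 150 subjects with 4 meals for decomposition recovery
(20 replicates), n = 200 for regression recovery and interval coverage
(50 replicates), 20 replicates for the conditional-vs-marginal R²
ordering — sizes at which the estimators' asymptotics are clearly visible
while the whole suite stays comfortably runnable on a laptop. The
pilot-calibrated integrated-squared-error thresholds and the mean-function
recovery tolerance (4.5 mg/dL at the default variance scale) were fixed
from simulations before being frozen into the tests.

## Known limitations

* The decomposition assumes a common, regular grid; sparse or irregular
  designs are out of scope.
* Coefficient smoothing's standard errors are mildly conservative (see
  above); exact simultaneous inference after smoothing would require the
  full covariance of the coefficient curve across `t`.
* R² variants are in-sample; a cross-validated extension is deliberately
  not provided here.
* The regression's random-effect structure is a random intercept
  function only.
* Timezone handling is naive UTC; meal logs recorded across DST changes
  need care upstream.
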