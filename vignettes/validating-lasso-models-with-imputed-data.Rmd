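---
title: "Validating lasso prediction models built on multiply imputed data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating lasso prediction models built on multiply imputed data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lassomi)
```

## The problem

Prognostic models for a continuous clinical outcome (the motivating setting
is predicting a quality-of-life score in COPD patients six months ahead) are
often built with the lasso: an L1 penalty shrinks regression coefficients
and sets some exactly to zero, trading a little apparent performance for
parsimony and protection against overfitting. Two practical complications
arise together in such studies:

1. **The apparent performance is optimistic.** The penalty is tuned to the
   data at hand, so the mean squared error (MSE) measured on the training
   data understates the error on new patients — shrinkage does not exempt
   the lasso from validation.
2. **Covariates are incomplete.** With multiple imputation (MI) the analyst
   holds M completed copies of the data, and it is not obvious how bootstrap
   internal validation should treat them.

`lassomi` implements the full pipeline — chained-equations imputation,
bootstrap penalty tuning, coefficient pooling, calibration, Harrell's
optimism bootstrap — and, as its core contribution, four resampling schemes
for combining that bootstrap with multiply imputed data, plus a simulation
framework that measures the bias of each scheme.

## Model building

For a completed data set the lasso estimate minimizes

$$\frac{1}{2n}\sum_{i=1}^n\left(y_i-\beta_0-x_i^\top\beta\right)^2
  +\lambda\,\lVert\beta\rVert_1 ,$$

with covariates standardized to unit variance internally, an unpenalized
intercept, and coefficients reported on the original scale (the `glmnet`
convention; the 1/(2n) factor makes penalty magnitudes comparable across
sample sizes). The penalty is chosen from a 40-value grid, log-spaced over
three decades down from the data-driven $\lambda_{\max}$ (the smallest
penalty with an all-zero solution). For each grid value, models are fit on
100 bootstrap resamples and scored on the original data; the same resamples
serve the whole grid so that the MSE profile is not blurred by resampling
noise. Two penalties are kept:

* **best** — the minimizer of the mean bootstrap MSE (ties toward the
  stronger penalty);
* **tolerance** — the strongest penalty whose mean MSE stays within 3% of
  that minimum, yielding a sparser model at a small performance cost.

With M imputed sets, tuning and fitting run separately in every set and the
final model averages the M coefficient vectors, zeros included — a covariate
selected in one set out of ten keeps a tenth of its value. Selection counts
(in how many sets each coefficient was nonzero) are recorded alongside.

```{r fit-example, eval = FALSE}
imp <- impute_mi(incomplete_data, m = 10, seed = 1)
model <- fit_pooled(imp, mode = "tolerance", seed = 2)
apparent_performance(model, imp)
```

## Performance: discrimination and calibration

Discrimination is the MSE; the apparent value is the mean of the pooled
model's MSE over the M completed sets. Calibration regresses the observed
outcome on the model's linear predictor, $y = \alpha_{LP} + \beta_{LP}
\cdot LP$; $\beta_{LP} = 1$ is perfect, $\beta_{LP} > 1$ means predictions
are over-shrunk (low predictions too high, high predictions too low), the
typical situation after strong penalization. A decile table of mean
predicted versus mean observed outcome is flagged against a ±0.5 band, the
minimal clinically important difference of the motivating score.
`recalibrate()` multiplies the slopes by a uniform shrinkage factor and
re-estimates the intercept by mean-matching; rescaling by the fitted
$\beta_{LP}$ restores a slope of exactly 1 on the same data.

## Internal validation with multiply imputed data

Harrell's bootstrap estimates the expected optimism: rebuild the entire
model in a bootstrap resample (grid, tuning, per-set fits, pooling — every
step), score it on the bootstrap data (`apparent*`) and on the original data
(`test*`), and average `optimism* = apparent* − test*` over B ≥ 100
iterations. The corrected performance is the apparent performance minus the
mean optimism; the shrinkage factor *s* is the mean of the per-iteration
calibration slopes of the original outcome on the bootstrap model's
predictor. With M imputed sets the resampling can be organized four ways:

1. **Shared subjects** — one bootstrap index vector applied to all M sets,
   so bootstrap sets differ only by imputed values.
2. **Independent subjects** — a separate index vector per imputed set.
3. **Single set** — pick one imputed set and run the classical procedure.
4. **Re-impute** — resample the *incomplete* data, then impute M times
   inside the bootstrap, replaying the imputation step itself.

The simulation study shows why the choice matters: approach 2 averages M
models built on effectively different resamples, which makes the pooled
bootstrap model artificially robust and drives its optimism estimate toward
zero — it badly underestimates optimism (running it on M identical copies
of complete data reproduces the artefact). Approaches 1 and 3 underestimate
moderately; approach 4 tracks the external gold standard best, at the price
of re-imputation cost and a slight upward bias.

## The simulation design

`sim_config()` encodes the reference data-generating process: 20
standard-normal covariates with eight nonzero pairwise correlations (e.g.
R(1,5) = 0.72, R(4,12) = −0.82), covariates 1–10 dichotomized (1,2,6,7 at
the 50th percentile, 3,4,8,9 at the 30th, 5,10 at the 20th), outcome
$y = 1.14 + x^\top\beta + \varepsilon$ with ten nonzero slopes (x6–x10,
x16–x20) and $\varepsilon \sim N(0, 1.74)$, so the irreducible MSE is
$1.74^2 = 3.028$. MCAR deletion hits x2, x7, x12, x17 at 20% per cell and
x3, x8, x13, x18 at 50%. `run_replicate()` fits both penalty modes,
measures apparent MSE, external MSE on a fresh independent complete draw of
the same size, external optimism (their difference), the calibration slope,
selection counts, and — on request — internal optimism under the classical
bootstrap (complete data) or any of the four approaches (incomplete data).

What the generator emulates: the covariate correlation structure, mixed
binary/continuous covariates, a sparse linear signal, homoscedastic noise,
and purely MCAR missingness with a complete outcome. What it does not:
missingness that depends on observed or unobserved values (MAR/MNAR),
longitudinal covariates, nonlinear or interaction effects, and outcome
missingness. Conclusions from passing tests therefore speak to the
resampling machinery, not to robustness against imputation-model
misspecification.

## Numerical and design choices

* **Dichotomization at theoretical quantiles.** Cuts use $\Phi^{-1}(p)$ of
  the standard normal rather than per-sample percentiles, so training and
  external data share the same cut; the indicator is 1 above the cut (a
  20th-percentile cut gives 80% ones). The alternative (per-sample cuts)
  would make the external design distribution drift with the training
  sample.
* **Imputation settings.** 5 chained-equation cycles, PMM donor pool of 5,
  visit order by increasing missingness fraction; parameter uncertainty
  enters through a normal draw around the fitted coefficients (with a
  scaled inverse-chi-squared residual variance draw for linear models).
  Logistic imputation falls back to a ridge-stabilized IRLS fit under
  separation — common in bootstrap resamples with duplicated rows — and to
  constant fill when only one class is observed; such events are counted
  and reported once rather than warned individually.
* **Shared tuning seed across imputed sets.** Within one model build, every
  set's penalty tuning uses the same bootstrap row indices. This removes
  between-set Monte Carlo noise from the per-set penalty choices and makes
  M identical sets reduce exactly to the single-set fit.
* **Ties and degenerate cases.** Argmin ties in tuning go to the stronger
  penalty; decile bins assign boundary ties to the lower bin; a constant
  outcome yields an intercept-only model; a constant linear predictor is a
  calibration error; non-finite bootstrap slopes are excluded from *s* with
  a warning.
* **Hierarchical seeding.** Every replicate's master seed spawns named
  substreams (data, missingness, imputation, fitting, external draw,
  validation), so replicates are independent, order-invariant, and
  individual stages can be aligned across settings — the zero-missingness
  WM replicate reproduces the NM replicate exactly.

## Problem sizes used in the bundled studies

Full-scale replication (1000 replicates with nested 100 x 100 bootstraps)
is a cluster-scale computation. The package's own studies — the acceptance
tests and `scripts/acceptance.R` — use reduced designs chosen to keep Monte
Carlo error comfortably inside the comparison tolerances: 200 NM replicates
(n = 250, grid 20, 30 tuning and 30 validation bootstraps), 100 (script) or
60 (tests) WM replicates with M = 10 for fit-and-external quantities, and
30 WM replicates with M = 10 (approach 4 re-imputing 5 sets per bootstrap),
B = 12 validation and 15 inner tuning bootstraps for the four-approach
comparison. The same code runs the full design by changing the counts.

## Limitations

Pooling by coefficient averaging is the reference procedure, not the only
one (majority-vote selection and group-lasso penalties are alternatives);
optimism is measured for MSE only, though the machinery accepts any model
with a linear predictor; and the imputation module implements the standard
chained-equations conventions rather than the full feature set of dedicated
MI software (no predictor-matrix restrictions, no multilevel models).
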