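---
title: "Methods: epigenetic age acceleration and prospective risk modelling"
author: "methylAging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epigenetic age acceleration and prospective risk modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

DNA methylation at age-correlated CpG sites supports a "clock": a penalized
linear predictor of chronological age from a beta-value profile. The gap
between predicted (DNAm) age and chronological age is a candidate biomarker
of biological aging. In whole blood that gap is confounded by cell
composition, because leukocyte proportions themselves drift with age (naive
CD8 T cells decline, granulocyte share rises). *Intrinsic epigenetic age
acceleration* (IEAA) removes that pathway: it is the residual from
regressing DNAm age on chronological age **and** seven imputed blood
cell-type abundances (naive CD8 T, exhausted CD8 T, plasma B, CD4 T, NK,
monocytes, granulocytes). A positive IEAA means methylation-older than
expected given age and blood composition.

`methylAging` implements the full analysis chain that takes a beta-value
matrix and a phenotype table to a prospective-risk statement: whether
standardized IEAA at baseline predicts incident disease (the motivating
application is lung cancer in a cohort of postmenopausal women aged 50-79)
under Cox proportional-hazards models. Because cohort methylation data of
this kind are access-controlled, every stage is validated on synthetic
cohorts with planted ground truth rather than on redistributed data.

## Models and procedures

### Beta values and the calibrated age scale

A beta value is `Max(M,0) / (Max(M,0) + Max(U,0) + 100)` for methylated and
unmethylated intensities; the +100 offset regularizes low-intensity probes
and makes the quantity deliberately scale-sensitive
(`betaFromIntensities()`). Clocks are fit on a transformed age scale,
logarithmic below a calibration knot (`adultAge`, default 20 years) and
linear above it; `transformAge()` / `inverseTransformAge()` are exact
inverses of one another. All cohort ages here are above the knot, where the
map is affine.

### Clock application and training

`applyClock()` evaluates `intercept + sum(coef_j * beta_j)` per sample,
joined by probe ID (never by position), and maps the result back to years.
Missing clock-probe betas are imputed with the probe's cohort mean (0.5
when a probe is absent everywhere); a sample observed at fewer than 80% of
the model's probes (configurable) is flagged `NA` rather than silently
mis-predicted. The package ships no published coefficient table - the
published clock's coefficients are copyrighted - so `trainClock()` fits an
elastic-net regression (mixing parameter 0.5, penalty by seeded 10-fold
cross-validation via glmnet, the same methodology class as the published
clock) on synthetic or user data, and `readClockModel()` accepts any
coefficient CSV in the standard two-column format with an `"(Intercept)"`
row.

### Cell-type deconvolution

`deconvolveCells()` estimates composition per sample by nonnegative least
squares against a reference signature matrix of pure cell-type profiles:
minimize ||beta - R w||^2 subject to w >= 0 and, in the default `"sum1"`
mode, sum(w) = 1 (the seven types treated as exhaustive for blood). The
sum constraint is imposed through an augmented penalty row (weight 1e4)
that determines the active support, followed by an exact
equality-constrained least-squares refit on that support, so row sums are
exact and nonnegativity is enforced by the solver rather than by post-hoc
clipping. A `"free"` mode (w >= 0 only) is provided because
abundance-style imputations need not sum to one; proportions are the
default. The original imputation method derives the exhausted-CD8 and
plasma-B scores from penalized regressions on a separate training
resource; this package treats all seven types uniformly through the
signature matrix, which is a documented divergence.

### IEAA

`computeIEAA()` is ordinary least squares of DNAm age on an intercept,
chronological age and the cell fractions. When fractions lie on the
simplex the design is exactly collinear with the intercept, so the
granulocyte column - the majority fraction, hence the natural reference -
is dropped. Residuals are standardized with the sample SD (n-1) over the
full analyzed cohort; stratified analyses reuse that full-cohort
standardization so hazard ratios stay on one scale. Samples without a
DNAm age are excluded listwise (with a count), and standardization happens
after exclusions. `eeaaResiduals()` gives the age-only residual for
comparison; its correlation with granulocyte fraction under planted
age-dependent composition is how the tests demonstrate what the cell
adjustment buys.

### Survival analysis

`coxFit()` maximizes the Cox partial likelihood with Breslow tie handling
(Efron behind a flag) and reports hazard ratios, Wald p-values, the
Breslow cumulative baseline hazard at covariate values zero, person-years,
and an explicitly labelled Cox-Snell-family R^2, `1 - exp(2(ll0 -
ll1)/n)`. Reference categories are never-smoker and white, so the model
reports Black, Hispanic, former- and current-smoker contrasts.
`stratifiedAnalysis()` refits within left-closed age decades ([50,60),
[60,70), 70+) or smoking strata, omitting pack-years for never smokers
(identically zero) and reporting event-free strata as unestimable instead
of dropping them. `predictIncidence()` evaluates `1 - exp(-H0(t)
exp(x'b))` for a covariate profile - e.g. age 75, white, current smoker,
30 pack-years, at standardized IEAA -1/0/+1 - extending the curve flat
beyond the last event time with a warning. `landmarkExclusion()` removes
cases within k years of baseline (censored subjects are kept);
`logisticSensitivity()` refits the covariate set as a logistic model,
which under a rare outcome approximates the hazard ratios.
`personYearsFromDays()` fixes the person-time convention: days/365.25 at
four decimals. A Bonferroni-style reporting threshold (0.05/6) is left to
the caller; the package does not gate output on it.

`kruskalWallis()` (tie-corrected H, chi-square reference) screens IEAA
against case status; `bicor()` is the biweight midcorrelation with Tukey
weights `(1-u^2)^2`, `u = (x - median)/(9 MAD)`, and a t-approximation
p-value. Zero-MAD inputs (e.g. pack-years in a mostly-never-smoking
cohort) fall back to Pearson with a warning, or error if the fallback is
disabled.

## The synthetic cohort generator

`simConfig()` fixes the study conditions; `simulateCohort()` draws a
cohort in four seeded stages (signatures, subjects, events, betas), each
deriving its stream from the one seed, so identical configs reproduce
bit-identically.

* **Covariates.** Ages uniform on 50-79; smoking prevalences 54.4 / 35.2 /
  10.4% (never/former/current); pack-years 0 for never smokers, gamma
  (shape 2) with means 19.4 and 25.9 for former and current; CHD
  prevalence 31%; race mix 48 / 32 / 20% (white/Black/Hispanic). These are
  the descriptive statistics of the motivating cohort.
* **Composition.** Cell fractions are Dirichlet around typical blood
  proportions (granulocytes 0.57, CD4 T 0.15, ...; concentration 40).
  `cellAgeEffect > 0` tilts granulocytes up and naive CD8 T down with age
  to plant the confounding that IEAA is supposed to remove.
* **Methylome.** Marker probes give each cell type a high (0.82-0.90)
  versus low (0.10-0.18) signature, so every pair of types is separated by
  at least 0.3 on each of their markers. Clock probes carry a logit-scale
  slope of 0.012-0.03 per year (random sign) applied to `true_age +
  true_acceleration`; the latent acceleration is Gaussian (SD 5 years),
  time-constant per subject - the analysis treats acceleration as a
  baseline scalar, so no trajectory model is attempted. Noise is Gaussian
  on the logit (M-value) scale, keeping betas strictly inside (0,1)
  without clipping artifacts.
* **Events.** Event times are exponential (constant baseline hazard - the
  simplest proportional-hazards model, chosen for its closed-form checks)
  with rate `baselineRate * exp(logHR * z + covariate effects)`, `z` the
  standardized acceleration; administrative censoring at 20 years. The
  default covariate log hazard ratios mirror the motivating study's full
  model (age 1.09/yr, former smoker 2.2, current smoker 6.2, pack-years
  1.03/py, CHD 0.8), the planted IEAA effect defaults to HR 1.5 per SD,
  and `baselineRate = 2.3e-4` was calibrated once so cumulative incidence
  is ~2.1%.

What the generator does **not** emulate: array chemistry and idat-level
artifacts, batch/plate effects, probe dropout beyond missing-value
handling, the two-phase case-control sampling of the original cohort
(with its survival-to-extraction condition), and non-proportional or
time-varying effects. Passing tests therefore demonstrate correctness of
the estimators under a clean proportional-hazards data-generating process,
not robustness to array artifacts or informative sampling.

## Numerical choices and edge cases

* Logits are clamped at 1e-12 from the boundaries as a guard; generator
  mixtures live well inside (0,1) so the clamp is never active in
  practice.
* Deconvolution refuses rank-deficient references (naming the collinear
  cell types) and samples with fewer non-missing shared probes than cell
  types; probes absent from the reference are ignored with a count.
* The IEAA regression refuses exact fits (zero residual variance leaves
  the z-score undefined) and rank-deficient designs not cured by the
  drop-one rule, naming the dependent columns.
* `coxFit()` flags likely monotone likelihoods (|log HR| > 12 or a
  non-finite standard error) with the offending covariate and marks the
  fit non-converged; constant covariates are a rank error before fitting.
* Age-stratum boundaries are left-closed ([50,60) etc.); the decade labels
  alone do not determine boundary handling, so the convention is fixed
  here and tested.
* Exact clock inversion cannot hold for cohort-simulated betas - their age
  signal is on the logit scale, so the clock's beta-linear predictor is
  only locally linear in age. `simulateClockBetas()` exists for exactly
  this reason: it constructs beta matrices whose linear predictor equals
  the transformed age, giving the machine-precision recovery check a
  clean target while the cohort generator keeps the more realistic
  logit-scale model.

## Problem sizes used in validation

The test suite and the acceptance script run entirely on generated data at
sizes chosen to make the stochastic checks statistically meaningful: 50
(suite) or 25 (script) end-to-end replicates at 2,000 analyzed subjects
each for recovery of the planted HR of 1.5 per SD and coverage of 95%
Wald intervals, and 500 (suite) or 200 (script) fast null replicates at
n = 500 with the event rate raised to ~90 events per replicate - the
regime in which the Wald test's nominal 5% level is an accurate
description; at ~50 events the same test is visibly anti-conservative,
a property of the Wald approximation rather than of the pipeline. The
held-out clock-accuracy check uses an acceleration SD of 2 years because
acceleration is irreducible error for chronological-age prediction: at the
cohort default of 5 years no predictor can exceed a correlation of ~0.86
with age, while the check's premise is an attainable 0.95 oracle.

## Known limitations

* The seven cell types are modelled symmetrically through one signature
  matrix; the original imputation's regression-calibrated scores for two
  of them are not reproduced.
* The elastic-net clock trained on synthetic cohorts is a stand-in for a
  published coefficient table; any real application should supply one via
  `readClockModel()`.
* No competing risks, left truncation, time-varying covariates or
  sampling-design weights; the time axis starts at baseline for everyone.
* Whether standardization should precede or follow exclusions is not
  identifiable from the motivating study; the package standardizes after
  exclusions (the order is a documented choice, not configurable per
  stratum).
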