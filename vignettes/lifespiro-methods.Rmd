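---
title: "Life-course lung-function trajectories: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Life-course lung-function trajectories: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spirometric lung function (FEV1, FVC and their ratio) rises through
childhood, peaks in early adulthood and declines thereafter. No single
cohort observes one person from age 4 to age 80, so life-course
trajectories must be assembled from several cohorts whose age windows
overlap — an *accelerated* cohort design. `lifespiro` implements the
full analysis chain for such pooled data: harmonisation and inclusion,
height-and-study standardisation, cross-classified mixed modelling with
spline age effects, year-by-year prediction, and a Bayesian
piecewise-linear changepoint analysis that reports breakpoint ages,
segment slopes in mL/year, plateau probabilities and the age at peak
lung function. Because individual-level cohort data cannot be
redistributed, the package ships a seeded synthetic-cohort generator
with known piecewise-linear ground truth, so the whole chain is testable
end to end.

## The synthetic accelerated cohort

`simulate_accelerated()` pools eight study designs whose age windows
jointly cover ages 4–80. Child birth cohorts visit at fixed ages
(jittered ±1 year); adult studies enrol at a uniformly distributed entry
age and revisit at fixed offsets, which is what spreads adult
observations continuously over each study's window, as rolling-enrolment
cohorts do. One study measures FEV1 but not FVC, mirroring a cohort that
collected slow rather than forced vital capacity.

An observed value is built as

```
value = truth_sex,parameter(age) + u_individual + u_study + u_birth-decade
        + covariate offsets + residual
```

with independent Gaussian random intercepts (defaults 0.25, 0.05, 0.03 L
and residual 0.15 L — the source publications do not report variance
components, so these are stated generator choices at scales typical of
within- and between-person spirometry variability). The ground-truth
curves are continuous piecewise-linear trajectories transcribed from the
published sex-specific breakpoint ages and segment slopes
(`default_trajectories()`); anchor values at age 4 are package choices
of plausible childhood volumes. Birth decade is `floor(birth_year/10)*10`
and is a *crossed* factor: decade effects are drawn once per pooled
simulation and shared across studies.

Asthma, active smoking and obesity follow first-order persistence chains
calibrated so the marginal prevalence tracks a configured age curve
(asthma highest in childhood, smoking peaking in young-to-mid adulthood,
obesity rising with age); each subtracts a small litre offset from FEV1
and/or FVC. BMI is drawn *consistently with* the simulated obesity state
via the same packaged child reference used downstream, so the
harmonisation round-trips. Heights follow a logistic growth curve per
sex; only their cross-sectional moments matter, since the generator adds
no height effect to lung function (standardisation is exercised as a
near no-op that must leave the signal untouched).

Attrition is `none` by default; `MCAR` drops each follow-up visit
independently, `MAR` retains a participant's follow-up with a logistic
probability in baseline age, asthma, smoking and obesity — participants
lost after baseline then fail the two-visit inclusion rule, which is
what the balancing weights correct.

What the generator does **not** emulate: real sampling frames and
response rates, equipment or protocol drift beyond an additive study
intercept, height effects on volume, or a ratio trajectory with its own
ground truth (the ratio is always the per-observation quotient of the
two simulated volumes, and because the published FEV1 and FVC rises are
similar in magnitude, the synthetic ratio's childhood course is flatter
than in real populations). Passing tests therefore demonstrate that the
*pipeline* recovers a known data-generating process of the right shape
and scale — not that any particular real-data estimate is correct.

## Harmonisation

`apply_inclusion()` first drops observations outside ages 4–80, then
drops participants with fewer than two visits that have lung function,
smoking, BMI and asthma status all present. It is idempotent.
`classify_persistence()` maps each participant's visit history to
`never` / `transient` / `persistent`; smoking counts as present when the
participant is an *active* smoker at the visit (a former smoker is not
"currently exposed", which matches the persistent-smoker semantics; this
is a documented interpretation). Obesity is BMI ≥ 30 from age 19 and a
BMI-for-age z-score ≥ +2 before that, against a packaged smooth
reference table labelled synthetic — it has WHO-like medians and SDs but
is constructed for this package, as the official growth reference is not
redistributed here.

`standardize_lf()` removes height and between-study differences within
each (sex, integer-age) stratum: the value is regressed on height and
study indicators and replaced by its residual re-centred at the stratum
mean fitted value. This leaves the litres scale intact (required for
mL/year slopes), zeroes the within-stratum height slope and study mean
differences, and preserves each stratum mean exactly. Strata below 10
observations merge with the nearest age stratum (lower age first on
ties). Prevalence curves use person-visits as the unit, Wilson 95%
intervals (stable at extreme prevalences) and LOESS with span 0.4
applied separately to the proportions and the interval bounds.

## The cross-classified mixed model

Observations (level 1) nest in participants (level 2), which are
cross-classified by study and 10-year birth cohort (level 3); all three
enter as random intercepts (`lme4::lmer` provides the estimation behind
`fit_ccmm()`). Fixed effects are a natural cubic spline in age plus
visit-level asthma, smoking (never/former/active, two indicators) and
obesity, each interacted with the spline so covariate effects can vary
with age. Groupings with fewer than two levels are dropped with a
warning; with none left the model collapses to (weighted) least squares.
Aliased columns from sparse covariate-by-spline cells are removed by QR
before fitting. Observation weights scale each observation's
contribution through the residual precision.

**Knot placement.** The six candidate internal knots are log-spaced over
ages 5–45 and taken in a fixed coarse-to-fine order, so the knot sets
nest across counts. Two deliberate choices are embedded here. First,
log-age placement over the growth-to-mid-adult span: lung function
changes fastest in childhood and adolescence (the reason reference
equations model age on the log scale), while late-adult decline is close
to linear and is handled by the spline tail; placing knots at quantiles
of an adult-heavy pooled cohort would leave the entire growth phase
without a single knot. Second, nesting: with nested candidate sets the
ML/BIC curve over knot counts decreases smoothly, so its elbow is well
defined rather than an artifact of which arbitrary knot layout a given
count happens to draw.

**Selection.** Knot counts are compared by ML (so BIC comparisons across
fixed-effect structures are valid) with BIC counting all estimated
parameters, and the elbow is the count maximising the perpendicular
distance below the chord joining the ends of the BIC curve (ties to the
smallest count). The default pipeline range is 2–6: a one-knot natural
spline cannot represent a growth–peak–decline curve at all, and
including it merely injects a cliff into the BIC geometry that drags the
elbow to the trivial answer. The selected model is refitted by REML.

**Prediction.** `predict_trajectory()` evaluates the fixed effects
(random effects at zero) on exactly the integer ages 4–80. The default
`marginal` mode averages over the empirical joint covariate distribution
at each (rounded) age, borrowing the nearest observed age where a grid
age has no data, so the curve describes the population as it is at each
age; `reference` mode fixes one covariate profile (used for
healthy-restricted comparisons). The 95% CI is the delta method on the
fixed-effect covariance — it reflects uncertainty in the mean curve, not
between-person spread; the separate SD column is the square root of the
summed variance components.

## The changepoint model

`decompose_trend()` fits a Bayesian piecewise-linear model to a
trajectory on the integer-age grid: each segment has its own intercept,
slope and noise variance under a conjugate normal–inverse-gamma prior
(τ = 10, a₀ = b₀ = 0.01 on the internally standardised scale); the
number of changepoints is uniform on 0–10 and, given the number, all
admissible positions (minimum segment length 2 grid points, the smallest
supporting a slope) are equally likely. Because segment evidences
factorise, the exact posterior over all segmentations is computed by
dynamic programming in O(k·n²) — no sampler is needed for the
segmentation itself — and seeded draws of segmentations and segment
lines are then taken by backward sampling, giving per-age slope samples
on the original scale. Seasonal terms of the decomposition this module
is modelled after are omitted: annual trajectories have no seasonal
component.

Reported quantities and the conventions behind them:

* **Breakpoint age.** A kink between two grid points is explained
  equally well by a segment boundary on either side, which would bias a
  boundary-position summary by about half a year. Each sampled
  breakpoint is therefore reported as the *intersection age of the two
  adjacent sampled segment lines* (clamped near the boundary), which
  recovers the kink exactly on noiseless input and gives sub-year
  resolution on smooth input.
* **Calling rule.** Candidates are local maxima of the per-age
  changepoint probability; the probability attached to a candidate
  aggregates the posterior mass over its basin (ages nearer to it than
  to any other maximum), because one true breakpoint on a smooth curve
  spreads its posterior over neighbouring years — a literal per-age
  threshold would rarely clear 0.5 even for a certain breakpoint. A
  candidate is called when that probability exceeds 0.5 **and** the
  trend-change magnitude exceeds 0.1.
* **Magnitude units.** The 0.1 threshold is applied to the change in
  slope of the *doubly standardised* series (values z-scored, age scaled
  by its SD), i.e. a dimensionless slope change. This is a documented
  interpretation — the threshold's units are not stated with the rule —
  and it is the reading under which a mid-adult change of ~14 mL/year on
  a series whose SD is ~1.5 L still clears 0.1, as the published
  mid-adult FVC breakpoint requires; a per-year z-slope reading would
  make that breakpoint undetectable by construction.
* **Slopes.** Segment slopes average the posterior per-age slope samples
  over the ages between called breakpoints and are reported in mL/year
  with 95% intervals from the per-draw segment means.
* **Plateaus and sign probabilities.** The zero band is 0.005
  standardised units per year (the rule's "slope being 0" needs a
  numerical zero; this is configurable). A plateau is a run of ages with
  P(|slope| ≤ band) > 0.5 sustained at least one year. The per-age
  increase/plateau/decrease probabilities are the sample fractions and
  sum to one.
* **Peak.** The called breakpoint with the highest trajectory value,
  reported with its 95% credible interval; with no called breakpoint the
  series maximum is returned with a boundary flag.

Noise is unknown per segment by default. Per-age SDs can be supplied
(`trend_series(..., sd = )`), replacing the NIG evidence with a
known-noise Gaussian evidence. This matters in one identified corner: a
~5-point flat segment cannot pin its own noise variance under the NIG
prior, so the default posterior stays agnostic about a short plateau
(probabilities around 0.2) rather than asserting one; when the noise
level is stated, detection flips on cleanly. Feeding the mixed model's
prediction standard errors in as known noise is *not* the default for
the pipeline, because the dominant deviation of the fitted curve from
piecewise linearity is smoothing structure, not sampling noise — treated
as known small noise it fragments the corners into many confident
micro-segments.

## Balancing weights for attrition

`cbps_weights()` computes just-identified covariate-balancing propensity
scores for retention: inverse-probability weights from a logistic score
whose coefficients solve the exact moment conditions that weighted
retained-group covariate means equal full-sample means (damped Newton on
standardised covariates; constants dropped; rank checked). The
just-identified form reproduces the balancing property that is the
method's point without the over-identified GMM machinery. MCAR mode
returns uniform weights. Participant-level weights are broadcast to
observations and enter the mixed model as precision weights.

## The pipeline and its problem sizes

`run_pipeline()` chains inclusion → persistence classification →
standardisation → knot selection → REML fit → prediction → changepoint
summary for each sex × parameter × stratum, refitting everything within
stratum for the stratified analyses. The FEV1/FVC ratio is computed per
observation before standardisation, never as a ratio of fitted curves.
Identical configuration and seed reproduce every output byte for byte.

The test suite and the acceptance script exercise recovery on cohorts of
about 2 400 participants per sex over five seeds — sizes at which the
recovered quantities are bias-limited rather than noise-limited (runs at
6 000 per sex give the same values), so larger simulations would add
runtime without information.

## Known limitations

* A natural cubic spline is C²-smooth and must round the sharp slope
  kinks of the synthetic ground truth over the inter-knot span. The
  called breakpoint then sits inside the rounded arc and short segments
  mix adjacent slope regimes, leaving a 5–15 mL/year downward bias on
  short growth-segment slopes and ~1 year of upward bias on peak age
  that does not shrink with sample size. Real trajectories are smooth at
  the knot scale, where this bias floor largely vanishes; on synthetic
  kinked truth it is the accuracy limit of the method, and recovered
  slopes should be read with that margin.
* Short plateaus (~5 years) are detectable only when the noise level is
  stated (above); the default model is conservative there.
* Prediction intervals cover fixed-effect uncertainty only.
* The synthetic ratio parameter has no independent ground truth and its
  childhood course is flatter than in real populations.
* Random slopes, autocorrelated residuals and heteroscedastic
  observation noise are out of scope.
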