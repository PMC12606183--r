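---
title: "Methods: thermal, habitat and competition limits on elevational ranges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal, habitat and competition limits on elevational ranges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elevrange)
```

## The scientific problem

Tropical montane birds often occupy narrow elevational bands, and three
classes of mechanism are commonly invoked to explain where those bands end:
thermal physiology (cold nights upslope become energetically unsustainable),
habitat structure (forest composition turns over along the gradient), and
interspecific competition (a dominant congener excludes its relative from
part of the gradient). `elevrange` implements a complete, testable pipeline
for weighing these hypotheses against repeated point-count data, together
with a synthetic-data module that emulates every input of such a field
study, so the entire chain of inference can be exercised with known ground
truth.

## The thermal-physiology model

**Lapse models.** Temperature loggers record air temperature every 30
minutes. `summarize_days()` splits each day at the approximate sunrise and
sunset times (05:30 and 18:30 by default) into a day window and its
complementary night, assigning each night to the calendar date on which it
begins. A night is only used when it has both post-sunset and pre-sunrise
readings, so the truncated first and last nights of a deployment are
dropped rather than biasing the night mean. `fit_lapse_model()` averages a
chosen daily response per logger across the season — one value per logger,
which avoids treating logger-days as independent replicates — and regresses
it on elevation by OLS. Temperature is regressed *on* elevation because the
fitted line is used to predict temperature at survey-point elevations.

**Thermoregulation.** Respirometry gives metabolic rate against chamber
temperature. `fit_thermoregulation()` fits the classical Scholander–Irving
broken stick: rate equals basal metabolic rate (BMR) at or above the lower
critical temperature $T_{lc}$, and rises linearly below it with slope
$C_{min}$ (minimum thermal conductance),

$$\mathrm{rate}(T) = \mathrm{BMR} + C_{min}\,\max(T_{lc} - T,\, 0).$$

Continuity at the breakpoint is enforced. The breakpoint is profiled over a
0.1 °C grid spanning the interior of the observed temperatures (excluding
the outermost two points on each side, where a breakpoint cannot be
distinguished from leverage); conditional on each candidate, (BMR,
$C_{min}$) come from least squares with $C_{min} \ge 0$. A flat
alternative — the sample mean, representing no measurable thermoregulatory
cost in the tested range — competes by AICc (the broken stick counts four
parameters including the residual variance, the flat model two); ties and
non-positive slopes go to the flat model. Grid search was chosen over
iterative segmented regression because it is deterministic, trivially
testable, and free of initialization sensitivity. Measurements are pooled
per species; per-bird pseudo-replication is a documented simplification
(the data carry 1–4 treatments per bird, too few for a stable per-bird
random effect).

**Costs and ceilings.** `cost_multiple()` expresses rate as a unitless
multiple of BMR (so the unnamed power units cancel), `nightly_cost_by_logger()`
averages it over each complete night's readings and then over the season —
night-only, because respirometry was nocturnal and night temperatures are
the energetically demanding ones — and `fit_cost_elevation()` regresses the
per-logger season means on elevation. The exact composition of a broken
stick with a linear lapse is piecewise linear in elevation; the straight
line absorbs the kink, and `piecewise_cost()` exposes the exact alternative
for comparison. `thermal_ceiling()` inverts the line at a sustainability
threshold, 2 × BMR by default — the conservative upper bound for sustained
thermoregulatory expenditure in tropical birds; it is configurable but must
exceed 1. Ceilings above the fitted elevation range are reported but
flagged as extrapolated; a non-positive slope yields no ceiling at all,
which is exactly what a thermally indifferent (flat) species produces.

## Habitat covariates

Three families, one row per survey plot:

* **Tree-type proportions** of cumulative stem diameter (broadleaf, tree
  fern, palm), which weight large stems more than counting would and sum to
  one wherever stems exist; a stem-free plot is missing, not zero.
* **Understorey density**: the mean number of touched 50 cm sections of a
  3 m pole over 40 placements, bounded in [0, 6].
* **Forest floor**: plot means of litter depth and soil-impact depth,
  standardized, scored on the first principal component of their 2 × 2
  correlation matrix, sign-oriented so deeper litter gives larger scores.
  The correlation (not covariance) matrix is used because the two depths
  live on different effective scales; quadrat values are averaged per plot
  before the PCA so plots, the modelling unit, are the PCA rows.

`assemble_covariates()` log10-transforms the understorey index toward
normality (guarding zeros with half the smallest positive value) and
z-scores every abundance covariate with the sample standard deviation, so
effect magnitudes are comparable; centres and scales are stored for
back-transformation.

## Competition covariates

`distance_to_congener()` computes each point's minimum planar Euclidean
distance to the congener's territory centroids (centroids, because no
boundary polygons exist; horizontal distance, because the territory map is
planimetric). `competition_terms()` z-scores the distance and its square as
a linked pair entered and dropped together, letting abundance respond
nonlinearly to proximity. `compare_competition_models()` contrasts a full
N-mixture fit containing the pair with a reduced fit lacking it, on
identical data and detection structure, by AICc and Akaike weight. The
reciprocal model (distance effect on the dominant species) is available but
off by default, mirroring its secondary scientific status.

## The abundance model

Counts from repeated visits are modelled with a zero-inflated Poisson
N-mixture model. Latent site abundance is
$N_i \sim \psi\,\delta_0 + (1-\psi)\,\mathrm{Poisson}(\lambda_i)$ with
$\log \lambda_i$ linear in site covariates; visit counts are binomial
thinnings $y_{ij} \sim \mathrm{Bin}(N_i, p_{ij})$ with
$\mathrm{logit}\, p_{ij}$ linear in visit covariates (minutes since
midnight, ordinal day, observer). The site likelihood marginalizes the
latent count up to a truncation bound $K$:

$$L_i = \psi\,[\,\text{all } y_{ij}=0\,] + (1-\psi) \sum_{N=0}^{K}
  \mathrm{Pois}(N;\lambda_i) \prod_{j \in \text{observed}}
  \mathrm{Bin}(y_{ij}; N, p_{ij}),$$

with missing visits skipped, never zero-filled. The sum is evaluated in log
space; the compiled kernel shares one $\log n!$ table across sites so each
latent-count step costs a table lookup per visit. Tests verify the kernel
against a brute-force probability-space enumeration on tiny problems and
against Poisson-thinning closed forms.

Numerical choices: $K$ defaults to the adaptive rule
$\max(y) + \max(100,\ 5\,e^{\max_i \log\hat\lambda_i})$, re-verified after
fitting (the suite asserts the log-likelihood moves by less than $10^{-6}$
between $K$ and $K+50$). Optimization is BFGS with finite-difference
gradients from fixed starting values: abundance intercept
$\log(\overline{\max_j y_{ij}} + 0.1)$, zeros elsewhere, $\psi$ starting at
0.1 on the logit scale. $\psi$ is a single scalar (no covariates on zero
inflation). Standard errors come from the inverse numerical Hessian and
p-values are Wald tests, reported only for converged fits. Numeric visit
covariates are z-scored internally for optimizer conditioning, so detection
estimates are per-SD effects. Solutions on the classic $\lambda \to \infty$,
$p \to 0$ ridge (or with pinned detection) are flagged as non-converged
rather than reported: they are not interior optima, and the bootstrap
excludes them.

**Two-step selection.** `select_detection_model()` fits every subset of the
candidate detection covariates against an intercept-only abundance model
and ranks by AICc (with $n$ = number of sites); exact ties go to fewer
parameters, then lexicographic order. The winning detection structure is
then fixed for the abundance models — the standard two-step protocol that
keeps the detection comparison from being confounded by abundance structure.

**Goodness of fit.** `bootstrap_gof()` simulates count matrices from the
fitted model on the observed missingness pattern, refits each, and compares
chi-square and sum-of-squares discrepancies with the
$(1 + \#\{\text{boot} \ge \text{obs}\})/(1 + B)$ convention;
$\hat c$ is the observed chi-square over the bootstrap mean. Expected
counts $E[y_{ij}] = (1-\psi)\lambda_i p_{ij}$ are floored at $10^{-3}$ in
the chi-square denominator; the identical rule for observed and bootstrap
statistics leaves calibration untouched while preventing near-zero cells
from dominating. Failed refits are excluded and counted, and more than 20 %
failures flags the result unreliable. The package reports $\hat c$ but
applies no correction, leaving that judgement to the analyst.

## What the synthetic-data module emulates

`elev_truth()` fixes the generative study conditions: a 1200–2200 m
gradient with a linear lapse (25 °C intercept, −0.0052 °C/m) and a diel
cycle built from two half-cosines with minimum at 05:30 and maximum at
13:30 (a pure sinusoid cannot peak eight hours after its trough; this is
the simplest continuous cycle that can), logger noise of 0.5 °C; four
species whose thermoregulation truths span a steep broken stick
(BMR 0.5, $T_{lc}$ 18 °C, $C_{min}$ 0.02) through to a flat no-cost
congener; respirometry with 1–4 treatments per bird drawn uniformly within
randomly chosen 6 °C bands between 5 and 34 °C (the uniform choice is an
assumption, not an asserted field truth); zero-inflated Poisson counts with
ragged 1–7 visits and four observers; logistic habitat gradients (tree-fern
share rising upslope, understorey thinning); and parapatric territory
mosaics with a ridge-jittered contact elevation near 1900 m, so the two
congeners never overlap on a ridge yet overlap when pooled across ridges.
Litter and soil-impact depths share a plot-level bivariate-normal effect
with correlation 0.6 and no elevation trend by default — a trend would
inflate the pooled litter–soil correlation beyond the stated generative
parameter; real forest floors do trend with elevation, which is one of the
ways the generator is simpler than the field.

The generator deliberately omits spatial autocorrelation in counts,
weather-dependent detection, respirometry gas traces (only rate–temperature
pairs are produced), and daytime thermoregulatory costing. Passing tests
therefore demonstrate that the estimators recover the parameters of this
idealized data-generating process at the study's scale — not that field
data satisfy those assumptions.

## Pipeline and problem sizes

`run_pipeline()` chains the stages end to end (simulation or user CSVs,
lapse models, thermoregulation fits, cost profiles and ceilings, habitat
and distance covariates, detection selection, abundance fits with the
full/reduced competition comparison for the subordinate congener, bootstrap
GOF) and writes tables, figures, a JSON-lines log, and a manifest that is
byte-identical across reruns with the same configuration and seed. Surveys
are generated from the measured habitat covariates and the *true* thermal
cost curve, while the fitted models see only the *estimated* cost — the
generation side never depends on the estimation side. A flat-thermoregulation
species' abundance model excludes the thermal-cost covariate, since a
constant cost of 1 carries no information (and is unscalable).

Default sizes mirror the emulated study: 83 points, 31 loggers, 45 logger
days, 1–7 visits; the test suite uses smaller replicates (30–300 sites,
199 bootstrap draws, 20–50 Monte-Carlo repetitions) chosen so each
stochastic check retains a comfortable margin under its stated bound. The
bootstrap default of 199 replicates is a desk-scale working default;
analyses intended for publication should raise `n_boot` substantially.

## Known limitations

* Per-species pooling of respirometry ignores repeated measures on birds.
* The breakpoint estimate cannot beat its 0.1 °C grid, and with noisy,
  shallow responses the flat model can win AICc even when a weak cost
  exists — a conservative bias.
* Wald intervals and AICc both rely on regular asymptotics; with very
  sparse counts the $\lambda$–$p$ ridge makes N-mixture likelihoods
  ill-behaved, which the divergence flag mitigates but does not cure.
* The habitat plot geometry is carried as metadata only; the indices do not
  depend on whether a "20 m² plot" is read as area or side length.
* Distances use territory centroids, not boundaries, and ignore elevation
  relief in the horizontal metric.
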