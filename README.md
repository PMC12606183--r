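# elevrange

What stops a tropical montane songbird from living higher up the mountain?
`elevrange` is an R package for weighing the three classic answers —
thermal physiology, habitat structure, and interspecific competition —
against repeated point-count survey data, the way field ornithologists and
quantitative ecologists actually collect it: temperature loggers along the
gradient, overnight respirometry, vegetation plots, territory maps of a
parapatric congener pair, and point counts with imperfect detection. A
first-class synthetic-data module emulates every one of those inputs with
known ground truth, so the full chain of inference is testable end to end.

## The models at the core

**Thermal physiology.** Respirometry is fitted with the Scholander–Irving
broken stick with continuity at the breakpoint,

> rate(T) = BMR + C_min · max(T_lc − T, 0),

by profiling T_lc over a 0.1 °C grid with conditional least squares
(C_min ≥ 0), against a flat no-cost alternative chosen by AICc. Logger
series are summarized into day/night statistics (day window 05:30–18:30)
and a linear elevational lapse T(e) = a + b·e is fitted to per-logger
season means. Composing the two gives the mean nightly thermoregulatory
cost in multiples of BMR at any elevation; inverting the fitted
cost–elevation line at a 2 × BMR sustainability threshold yields each
species' *thermal ceiling*.

**Abundance.** Counts y_ij from repeated visits j to site i follow a
zero-inflated Poisson N-mixture model:

> N_i ~ ψ·δ₀ + (1 − ψ)·Poisson(λ_i),  log λ_i = x_iᵀβ
> y_ij | N_i ~ Binomial(N_i, p_ij),  logit p_ij = v_ijᵀα

with the latent count marginalized up to an adaptive truncation K in a
compiled log-space kernel. Detection covariates (minutes since midnight,
ordinal day, observer) are chosen first by all-subsets AICc against an
intercept-only abundance model; abundance covariates (tree-type
proportions of cumulative diameter, log touch-pole understorey index,
forest-floor PC1, estimated thermal cost, and a z-scored quadratic
distance-to-congener pair) enter second. Goodness of fit is a parametric
bootstrap of chi-square and sum-of-squares discrepancies with c-hat
reported; the competition hypothesis is a full-versus-reduced AICc
comparison dropping the distance pair.

## Worked example

Simulate the field study at its native scale and walk the thermal
hypothesis end to end:

```r
library(elevrange)
truth <- elev_truth(seed = 1)

loggers <- generate_loggers(truth, n_loggers = 31,
                            elevation_range = c(1200, 2200), days = 45)
lapse <- fit_lapse_model(summarize_days(loggers), "night_mean")
lapse
#> <lapse_model: night_mean>
#>   T = 23.612 -0.00521 * elevation (degC, m); r = -1.000; n = 31 loggers

resp <- generate_respirometry(truth$thermo$C_mexicanus, n_birds = 28,
                              noise_sd = 0.025, species = "C_mexicanus",
                              seed = 4)
thermo <- fit_thermoregulation(resp)
thermo
#> <thermo_model: C_mexicanus (broken_stick)>
#>   BMR = 0.501, T_lc = 17.2 degC, C_min = 0.02205 per degC; n = 74
#>   AICc: broken-stick -328.86, flat -130.54

profile <- fit_cost_elevation(nightly_cost_by_logger(thermo, loggers),
                              threshold = 2, species = "C_mexicanus")
thermal_ceiling(profile)
#> # A tibble: 1 x 3
#>   ceiling_m extrapolated reason
#>       <dbl> <lgl>        <chr>
#> 1     6390. TRUE         ok
```

Read: the night-time lapse is −5.2 °C per km (r ≈ −1), the fitted broken
stick recovers the generating physiology (truth: BMR 0.5, T_lc 18,
C_min 0.02), and the 2 × BMR threshold is not reached until ~6400 m —
far above the 2200 m gradient, so thermal costs cannot explain this
species' upper limit (the flag marks the ceiling as an extrapolation).
`autoplot(profile)` draws the cost-versus-elevation figure with the
threshold line.

The competition hypothesis for the subordinate congener:

```r
pts  <- simulate_points(83, c(1200, 2200), seed = 2)
terr <- generate_territories(truth, ridges = 5, territories_per_ridge = 6,
                             seed = 3)
hab  <- generate_habitat(truth, pts, seed = 5)
site_tab <- assemble_covariates(
  tree_proportions(hab, pts) |>
    dplyr::inner_join(understorey_index(hab), by = "point_id") |>
    dplyr::inner_join(forest_floor_index(hab), by = "point_id"),
  distances = distance_to_congener(pts, terr, species = "C_mexicanus"))

counts <- generate_survey(truth, pts, visits_per_point = c(1, 7),
                          site_covariates = site_tab,
                          species = "C_frantzii", seed = 6)
sel  <- select_detection_model(counts)
full <- fit_nmixture(counts, nmix_spec(
  ~ pct_tree_fern + pct_palm + dist_congener + dist_congener_sq,
  sel$best_detection))
reduced <- fit_nmixture(counts, nmix_spec(~ pct_tree_fern + pct_palm,
                                          sel$best_detection))
compare_competition_models(full, reduced)
#> <nmix_comparison>
#>    model  k    logLik     AICc       weight
#>     full 11 -149.5519 324.8221 9.999830e-01
#>  reduced  9 -163.1605 346.7868 1.699954e-05
#>   delta AICc (reduced - full) = 21.965; preferred: full
```

The model containing the quadratic distance-to-congener pair wins by 22
AICc units (Akaike weight ≈ 1), the expected signature of competitive
exclusion given that the generator put a positive distance effect on this
species. `bootstrap_gof(full, n_boot = 199, seed = 8)` gives chi-square
p = 0.175 and c-hat = 1.17: no evidence of misfit or serious
over-dispersion. Fitted objects support `tidy()`, `glance()` and
`autoplot()`.

`run_pipeline(pipeline_config(out_dir = "results", seed = 1))` runs every
stage for all four species and writes the tables, figures, a JSON-lines
log and a deterministic `manifest.json`;
`inst/scripts/elevrange.R` is a thin command-line wrapper around it.

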