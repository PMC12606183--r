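# Generators: deterministic limits, closed-form Monte-Carlo checks, and
# reproducibility.

test_that("logger generator reproduces the lapse line in the noise-free limit", {
  tr <- elev_truth(lapse_intercept = 25, lapse_slope = -0.005,
                   diel_amplitude = 0, logger_noise_sd = 0)
  lg <- generate_loggers(tr, n_loggers = 2, elevation_range = c(1000, 2000),
                         days = 1)
  expect_equal(nrow(lg), 96)  # 48 readings per logger per day
  at2000 <- lg$temp_c[lg$elevation == 2000]
  expect_equal(at2000, rep(15, 48), tolerance = 1e-12)
  # lapse line exact at every elevation
  for (e in unique(lg$elevation)) {
    expect_equal(unique(lg$temp_c[lg$elevation == e]), 25 - 0.005 * e)
  }
})

test_that("logger generator obeys its stated generative model (Monte Carlo)", {
  tr <- elev_truth(lapse_intercept = 25, lapse_slope = -0.005,
                   diel_amplitude = 0, logger_noise_sd = 0.5, seed = 31)
  lg <- generate_loggers(tr, n_loggers = 2, elevation_range = c(1500, 1800),
                         days = 30)
  one <- lg[lg$elevation == 1500, ]
  mu <- 25 - 0.005 * 1500
  se <- 0.5 / sqrt(nrow(one))
  expect_lt(abs(mean(one$temp_c) - mu), 3 * se)
})

test_that("logger generator validates inputs and is bit-reproducible", {
  tr <- elev_truth()
  expect_error(generate_loggers(tr, 1, c(1000, 2000), 2), "n_loggers")
  expect_error(generate_loggers(tr, 3, c(2000, 1000), 2), "ordered")
  expect_error(generate_loggers(tr, 3, c(1000, 2000), 0), "days")
  a <- generate_loggers(tr, 3, c(1000, 2000), 2, seed = 5)
  b <- generate_loggers(tr, 3, c(1000, 2000), 2, seed = 5)
  expect_identical(a, b)
})

test_that("respirometry generator applies the piecewise response exactly", {
  # noiseless broken stick: measured rate = BMR + C_min * (T_lc - T) below T_lc
  tm <- thermo_truth(bmr = 0.5, t_lc = 18, c_min = 0.02)
  d <- generate_respirometry(tm, n_birds = 30, treatments_per_bird = c(1, 4),
                             noise_sd = 0, seed = 4)
  expect_equal(d$metabolic_rate,
               0.5 + 0.02 * pmax(18 - d$chamber_temp_c, 0), tolerance = 1e-12)
  # the documented worked value: 8 degC -> 0.70
  expect_equal(0.5 + 0.02 * (18 - 8), 0.7)
  # flat truth: BMR everywhere
  df <- generate_respirometry(thermo_truth(bmr = 0.5), 10, c(1, 4), 0, seed = 4)
  expect_true(all(df$metabolic_rate == 0.5))
  # row-count bounds and band range
  expect_gte(nrow(d), 30)
  expect_lte(nrow(d), 120)
  expect_true(all(d$chamber_temp_c >= 5 & d$chamber_temp_c <= 34))
  expect_error(generate_respirometry(tm, 5, c(1, 4), noise_sd = -1), "noise_sd")
})

test_that("survey generator collapses correctly at detection extremes", {
  pts <- simulate_points(50, c(1200, 2200), seed = 1)
  sc <- tibble::tibble(point_id = pts$point_id)
  # p = 1: every count equals its site's latent N; pooled counts Poisson(1)
  tr1 <- elev_truth(psi = 0, abundance = list(sp = c("(Intercept)" = 0)),
                    detection = c("(Intercept)" = Inf, minutes = 0, day = 0,
                                  observer2 = 0, observer3 = 0, observer4 = 0))
  cd <- generate_survey(tr1, pts, visits_per_point = 3, sc, seed = 9)
  N <- attr(cd, "latent_n")
  expect_true(all(cd$y == matrix(N, nrow(cd$y), ncol(cd$y)), na.rm = TRUE))
  # p = 0: all observed counts zero regardless of N
  tr0 <- elev_truth(psi = 0, abundance = list(sp = c("(Intercept)" = 1.5)),
                    detection = c("(Intercept)" = -Inf, minutes = 0, day = 0,
                                  observer2 = 0, observer3 = 0, observer4 = 0))
  cd0 <- generate_survey(tr0, pts, visits_per_point = 3, sc, seed = 9)
  expect_true(all(cd0$y == 0, na.rm = TRUE))
})

test_that("fraction of all-zero histories matches the Poisson-thinning closed form", {
  # psi = 0.4, lambda = 3, p = 0.7, 2000 sites, 4 visits
  psi <- 0.4; lambda <- 3; p <- 0.7; J <- 4
  pts <- simulate_points(2000, c(1200, 2200), seed = 2)
  sc <- tibble::tibble(point_id = pts$point_id)
  tr <- elev_truth(psi = psi,
                   abundance = list(sp = c("(Intercept)" = log(lambda))),
                   detection = c("(Intercept)" = qlogis(p), minutes = 0, day = 0,
                                 observer2 = 0, observer3 = 0, observer4 = 0))
  cd <- generate_survey(tr, pts, visits_per_point = J, sc, seed = 77)
  frac0 <- mean(apply(cd$y, 1, function(r) all(r == 0, na.rm = TRUE)))
  expected <- psi + (1 - psi) * exp(-lambda * (1 - (1 - p)^J))
  se <- sqrt(expected * (1 - expected) / 2000)
  expect_lt(abs(frac0 - expected), 3 * se)
})

test_that("survey marginal moment E[y] = (1 - psi) * lambda * p holds", {
  psi <- 0.3; lambda <- 2; p <- 0.6
  pts <- simulate_points(3000, c(1200, 2200), seed = 3)
  sc <- tibble::tibble(point_id = pts$point_id)
  tr <- elev_truth(psi = psi,
                   abundance = list(sp = c("(Intercept)" = log(lambda))),
                   detection = c("(Intercept)" = qlogis(p), minutes = 0, day = 0,
                                 observer2 = 0, observer3 = 0, observer4 = 0))
  cd <- generate_survey(tr, pts, visits_per_point = 2, sc, seed = 13)
  yv <- cd$y[!is.na(cd$y)]
  mu <- (1 - psi) * lambda * p
  # Var(y) for the ZIP-binomial mixture exceeds the Poisson variance; use
  # the empirical SE, which is valid for a mean either way
  se <- sd(yv) / sqrt(length(yv))
  expect_lt(abs(mean(yv) - mu), 3 * se)
})

test_that("habitat generator respects degenerate gradients and bounds", {
  pts <- simulate_points(40, c(1200, 2200), seed = 4)
  # transition pushed far above the gradient: tree-fern share exactly 0
  tr <- elev_truth()
  tr$habitat$fern_mid <- 1e5
  tr$habitat$fern_scale <- 10
  hb <- generate_habitat(tr, pts, seed = 6)
  expect_false(any(hb$stems$type == "tree_fern"))
  # touch counts always integers in [0, 6]
  hb2 <- generate_habitat(elev_truth(), pts, seed = 7)
  expect_true(all(hb2$touches$touches %in% 0:6))
  expect_equal(nrow(hb2$touches), 40 * nrow(pts))
  expect_equal(nrow(hb2$quadrats), 5 * nrow(pts))
})

test_that("litter and soil depths are positively correlated as parameterized", {
  tr <- elev_truth()
  pts <- simulate_points(500, c(1200, 2200), seed = 5)
  hb <- generate_habitat(tr, pts, seed = 8)
  pm <- dplyr::summarise(dplyr::group_by(hb$quadrats, point_id),
                         litter = mean(litter_mm), soil = mean(soil_mm))
  r_obs <- cor(pm$litter, pm$soil)
  # expected plot-mean correlation: between-plot correlation attenuated by
  # within-plot quadrat noise averaged over 5 quadrats
  sig <- tr$habitat$floor_sd; qsd <- tr$habitat$quadrat_sd
  r_expect <- tr$habitat$floor_cor * sig[["litter"]] * sig[["soil"]] /
    sqrt((sig[["litter"]]^2 + qsd[["litter"]]^2 / 5) *
         (sig[["soil"]]^2 + qsd[["soil"]]^2 / 5))
  se <- (1 - r_expect^2) / sqrt(500)
  expect_gt(r_obs, 0)
  expect_lt(abs(r_obs - r_expect), 3 * se)
})

test_that("territory mosaics are parapatric per ridge with jittered contacts", {
  tr <- elev_truth(ridge_jitter_sd = 0)
  tm <- generate_territories(tr, ridges = 5, territories_per_ridge = 4, seed = 2)
  expect_equal(dplyr::n_distinct(round(tm$contact_elevation, 9)), 1)
  trj <- elev_truth(ridge_jitter_sd = 100)
  tmj <- generate_territories(trj, ridges = 10, territories_per_ridge = 5, seed = 3)
  # strict parapatry on every ridge
  by_ridge <- split(tmj, tmj$ridge)
  for (rd in by_ridge) {
    lo <- rd$elevation[rd$species == "C_mexicanus"]
    hi <- rd$elevation[rd$species == "C_frantzii"]
    expect_lt(max(lo), min(hi))
  }
  # pooled ranges overlap in at least 1 of 20 seeded replicates
  overlaps <- vapply(1:20, function(s) {
    m <- generate_territories(trj, 10, 5, seed = 100 + s)
    lo <- m$elevation[m$species == "C_mexicanus"]
    hi <- m$elevation[m$species == "C_frantzii"]
    max(lo) > min(hi)
  }, logical(1))
  expect_gte(sum(overlaps), 1)
})

test_that("truth constructor enforces its invariants", {
  expect_error(elev_truth(lapse_slope = 0.001), "negative")
  expect_error(elev_truth(psi = 1), "psi")
  expect_error(elev_truth(diel_amplitude = -1), "diel_amplitude")
  expect_error(thermo_truth(bmr = -0.1), "bmr")
  expect_error(thermo_truth(bmr = 0.5, t_lc = 18, c_min = 0), "c_min")
})
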