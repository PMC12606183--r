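# ZIP N-mixture likelihood, fitting, AICc, and detection selection.

test_that("likelihood matches Poisson-thinning closed forms", {
  # one site, one visit, lambda = 1, p = 0.5, K = 50
  y0 <- matrix(0L, 1, 1)
  cd0 <- make_count_data(y0)
  sp_pois <- nmix_spec(~1, ~1, zip = FALSE, K = 50)
  # y = 0: P = exp(-lambda * p) = exp(-0.5)
  expect_equal(zip_nmixture_loglik(c(0, 0), cd0, sp_pois), -0.5,
               tolerance = 1e-10)
  # y = 1: P = (lambda p) exp(-lambda p) = 0.5 exp(-0.5)
  cd1 <- make_count_data(matrix(1L, 1, 1))
  expect_equal(zip_nmixture_loglik(c(0, 0), cd1, sp_pois),
               log(0.5 * exp(-0.5)), tolerance = 1e-10)
  # zero inflation: psi = 0.2, y = 0
  sp_zip <- nmix_spec(~1, ~1, zip = TRUE, K = 50)
  expect_equal(zip_nmixture_loglik(c(0, 0, qlogis(0.2)), cd0, sp_zip),
               log(0.2 + 0.8 * exp(-0.5)), tolerance = 1e-10)
  # perfect detection, single visit: Poisson pmf exactly
  for (yv in 0:4) {
    cdy <- make_count_data(matrix(as.integer(yv), 1, 1))
    ll <- zip_nmixture_loglik(c(log(2), 30), cdy,
                              nmix_spec(~1, ~1, zip = FALSE, K = 60))
    expect_equal(ll, dpois(yv, 2, log = TRUE), tolerance = 1e-8)
  }
})

test_that("all-zero history probability equals psi + (1-psi) exp(-lambda(1-(1-p)^J))", {
  lambda <- 1.3; p <- 0.45; psi <- 0.25
  for (J in 1:4) {
    y <- matrix(0L, 1, J)
    cd <- make_count_data(y)
    ll <- zip_nmixture_loglik(c(log(lambda), qlogis(p), qlogis(psi)), cd,
                              nmix_spec(~1, ~1, zip = TRUE, K = 80))
    closed <- psi + (1 - psi) * exp(-lambda * (1 - (1 - p)^J))
    expect_equal(exp(ll), closed, tolerance = 1e-10)
  }
})

test_that("likelihood equals brute-force enumeration on tiny problems", {
  set.seed(123)
  for (rep in 1:30) {
    n <- sample(1:3, 1); J <- sample(1:2, 1); K <- sample(10:15, 1)
    y <- matrix(sample(0:3, n * J, replace = TRUE,
                       prob = c(0.5, 0.3, 0.15, 0.05)), n, J)
    if (J == 2 && runif(1) < 0.4) y[sample(n, 1), 2] <- NA  # missing visit
    x <- rnorm(n)
    minutes <- matrix(runif(n * J, 300, 540), n, J)
    b <- rnorm(2, 0, 0.7); a <- rnorm(2, 0, 0.7); psi <- runif(1, 0, 0.6)
    cd <- make_count_data(y, minutes = minutes,
                          sites = tibble::tibble(x = x))
    spec <- nmix_spec(~x, ~minutes, zip = TRUE, K = K)
    ll <- zip_nmixture_loglik(c(b, a, qlogis(psi)), cd, spec)
    lambda <- exp(b[1] + b[2] * x)
    pm <- plogis(a[1] + a[2] * zscore_cells(minutes, y))
    expect_equal(ll, oracle_zip_loglik(y, lambda, pm, psi, K),
                 tolerance = 1e-10)
  }
})

test_that("single-site likelihood normalizes over all counts", {
  lambda <- 2.3; p <- 0.4; psi <- 0.35; K <- 120
  total <- sum(vapply(0:K, function(yv) {
    cd <- make_count_data(matrix(as.integer(yv), 1, 1))
    exp(zip_nmixture_loglik(c(log(lambda), qlogis(p), qlogis(psi)), cd,
                            nmix_spec(~1, ~1, zip = TRUE, K = K)))
  }, numeric(1)))
  expect_equal(total, 1, tolerance = 1e-8)
})

test_that("likelihood skips missing visits rather than zero-filling", {
  y_missing <- matrix(c(1L, NA, 2L, 0L), 2, 2)
  cd_m <- make_count_data(y_missing)
  par <- c(log(2), qlogis(0.5), qlogis(0.2))
  ll_m <- zip_nmixture_loglik(par, cd_m, nmix_spec(~1, ~1, K = 60))
  # oracle with the same missingness
  pm <- matrix(0.5, 2, 2)
  expect_equal(ll_m, oracle_zip_loglik(y_missing, c(2, 2), pm, 0.2, 60),
               tolerance = 1e-10)
  # and it differs from zero-filling the gap
  y_fill <- y_missing; y_fill[1, 2] <- 0L
  ll_f <- zip_nmixture_loglik(par, make_count_data(y_fill),
                              nmix_spec(~1, ~1, K = 60))
  expect_gt(abs(ll_m - ll_f), 1e-6)
})

test_that("K below the maximum count and bad inputs are rejected", {
  y <- matrix(c(0L, 7L), 1, 2)
  cd <- make_count_data(y)
  expect_error(zip_nmixture_loglik(c(0, 0, 0), cd, nmix_spec(~1, ~1, K = 5)),
               "below the maximum")
  expect_error(fit_nmixture(cd, nmix_spec(~1, ~1, K = 5)), "below the maximum")
  expect_identical(as.numeric(zip_nmixture_loglik(c(NA, 0, 0), cd,
                                                  nmix_spec(~1, ~1, K = 50))),
                   -Inf)
  expect_error(nmix_spec(~1, ~ elevation), "restricted")
})

test_that("AICc follows the small-sample formula with its degenerate case", {
  expect_equal(aicc(-5, k = 2, n = 10), 14 + 12 / 7, tolerance = 1e-12)
  expect_equal(aicc(-5, k = 2, n = 1e9), 14, tolerance = 1e-6)
  expect_warning(val <- aicc(-5, k = 2, n = 3), "undefined")
  expect_identical(val, Inf)
})

test_that("fitting recovers generating parameters and is exchangeable", {
  tr <- elev_truth(psi = 0,
                   abundance = list(sp = c("(Intercept)" = log(3))),
                   detection = c("(Intercept)" = qlogis(0.6), minutes = 0,
                                 day = 0, observer2 = 0, observer3 = 0,
                                 observer4 = 0))
  pts <- simulate_points(300, seed = 30)
  sc <- tibble::tibble(point_id = pts$point_id)
  cd <- generate_survey(tr, pts, 4, sc, seed = 31)
  fit <- fit_nmixture(cd, nmix_spec(~1, ~1, zip = FALSE))
  est <- fit$coefficients
  expect_true(fit$converged)
  expect_lt(abs(est$estimate[1] - log(3)), 3 * est$se[1])
  expect_lt(abs(est$estimate[2] - qlogis(0.6)), 3 * est$se[2])
  # permuting site order leaves estimates identical
  perm <- sample(nrow(cd$counts_long))
  cd_perm <- count_data(cd$counts_long[perm, ], sc)
  fit2 <- fit_nmixture(cd_perm, nmix_spec(~1, ~1, zip = FALSE))
  expect_equal(fit2$coefficients$estimate, est$estimate, tolerance = 1e-8)
})

test_that("adaptive truncation is stable: K and K + 50 agree", {
  tr <- elev_truth(psi = 0.2, abundance = list(sp = c("(Intercept)" = 1)),
                   detection = c("(Intercept)" = 0.5, minutes = 0, day = 0,
                                 observer2 = 0, observer3 = 0, observer4 = 0))
  pts <- simulate_points(100, seed = 33)
  cd <- generate_survey(tr, pts, 3, tibble::tibble(point_id = pts$point_id),
                        seed = 34)
  fit <- fit_nmixture(cd, nmix_spec(~1, ~1))
  ll_K <- zip_nmixture_loglik(fit$par, cd, fit$spec, K = fit$K)
  ll_K50 <- zip_nmixture_loglik(fit$par, cd, fit$spec, K = fit$K + 50L)
  expect_lt(abs(ll_K - ll_K50), 1e-6)
})

test_that("likelihood is invariant to observer relabelling", {
  tr <- elev_truth(psi = 0.1, abundance = list(sp = c("(Intercept)" = 1)),
                   detection = c("(Intercept)" = 0.3, minutes = 0, day = 0,
                                 observer2 = -0.4, observer3 = 0.4, observer4 = 0))
  pts <- simulate_points(80, seed = 35)
  cd <- generate_survey(tr, pts, c(2, 5), tibble::tibble(point_id = pts$point_id),
                        seed = 36)
  f1 <- fit_nmixture(cd, nmix_spec(~1, ~observer))
  relabel <- c(obs1 = "obsD", obs2 = "obsC", obs3 = "obsB", obs4 = "obsA")
  long2 <- dplyr::mutate(cd$counts_long, observer = relabel[observer])
  f2 <- fit_nmixture(count_data(long2, tibble::tibble(point_id = pts$point_id)),
                     nmix_spec(~1, ~observer))
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
})

test_that("adding a covariate never decreases the maximized log-likelihood", {
  set.seed(40)
  tr <- elev_truth(psi = 0.15,
                   abundance = list(sp = c("(Intercept)" = 0.9, z1 = 0.4)),
                   detection = c("(Intercept)" = 0.4, minutes = -0.3, day = 0,
                                 observer2 = 0, observer3 = 0, observer4 = 0))
  pts <- simulate_points(120, seed = 41)
  sc <- tibble::tibble(point_id = pts$point_id, z1 = rnorm(120), z2 = rnorm(120))
  cd <- generate_survey(tr, pts, c(2, 5), sc, seed = 42)
  ll0 <- fit_nmixture(cd, nmix_spec(~z1, ~minutes))$logLik
  ll1 <- fit_nmixture(cd, nmix_spec(~ z1 + z2, ~minutes))$logLik
  ll2 <- fit_nmixture(cd, nmix_spec(~ z1 + z2, ~ minutes + day))$logLik
  expect_gte(ll1, ll0 - 1e-6)
  expect_gte(ll2, ll1 - 1e-6)
})

test_that("rank-deficient designs are rejected with the offending columns", {
  tr <- elev_truth(psi = 0.1, abundance = list(sp = c("(Intercept)" = 1)),
                   detection = c("(Intercept)" = 0.3, minutes = 0, day = 0,
                                 observer2 = 0, observer3 = 0, observer4 = 0))
  pts <- simulate_points(40, seed = 43)
  sc <- tibble::tibble(point_id = pts$point_id, a = rnorm(40))
  sc$b <- 2 * sc$a
  cd <- generate_survey(tr, pts, 3, sc, seed = 44)
  expect_error(fit_nmixture(cd, nmix_spec(~ a + b, ~1)), "collinear.*b")
})

test_that("Wald intervals for the abundance intercept achieve near-nominal coverage", {
  tr <- elev_truth(psi = 0,
                   abundance = list(sp = c("(Intercept)" = log(3))),
                   detection = c("(Intercept)" = qlogis(0.6), minutes = 0,
                                 day = 0, observer2 = 0, observer3 = 0,
                                 observer4 = 0))
  pts <- simulate_points(300, seed = 50)
  sc <- tibble::tibble(point_id = pts$point_id)
  covered <- vapply(1:100, function(s) {
    cd <- generate_survey(tr, pts, 4, sc, seed = 5000 + s)
    fit <- fit_nmixture(cd, nmix_spec(~1, ~1, zip = FALSE))
    if (!fit$converged) return(NA)
    est <- fit$coefficients$estimate[1]; se <- fit$coefficients$se[1]
    abs(est - log(3)) < 1.96 * se
  }, logical(1))
  expect_gte(sum(covered, na.rm = TRUE), 88)
})

test_that("detection selection returns a complete, ordered ranking", {
  tr <- elev_truth(psi = 0.1, abundance = list(sp = c("(Intercept)" = 1)),
                   detection = c("(Intercept)" = 0.4, minutes = -1.2, day = 0,
                                 observer2 = 0, observer3 = 0, observer4 = 0))
  pts <- simulate_points(80, seed = 52)
  cd <- generate_survey(tr, pts, c(2, 5), tibble::tibble(point_id = pts$point_id),
                        seed = 53)
  sel1 <- select_detection_model(cd, candidates = "minutes")
  expect_equal(nrow(sel1$ranking), 2)  # one candidate -> two subsets
  sel <- select_detection_model(cd)
  expect_equal(nrow(sel$ranking), 8)
  expect_true(all(diff(sel$ranking$AICc) >= 0))
  expect_true(grepl("minutes", sel$best_label))
  expect_error(select_detection_model(cd, candidates = "wind"), "Invalid")
})
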