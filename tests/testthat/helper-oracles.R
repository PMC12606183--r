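# Independent oracles and tiny-fixture builders used across the suite.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Brute-force ZIP N-mixture likelihood: direct probability-space enumeration
# over the latent abundance of every site (no log-sum-exp, no compiled
# code). Only feasible for tiny problems; serves as the independent oracle
# for the package's likelihood.
oracle_zip_loglik <- function(y, lambda, p, psi, K) {
  total <- 0
  for (i in seq_len(nrow(y))) {
    obs <- which(!is.na(y[i, ]))
    cond <- 0
    for (N in 0:K) {
      term <- dpois(N, lambda[i])
      for (j in obs) term <- term * dbinom(y[i, j], N, p[i, j])
      cond <- cond + term
    }
    Li <- (1 - psi) * cond + if (all(y[i, obs] == 0)) psi else 0
    total <- total + log(Li)
  }
  total
}

# Build a count_data object from matrices (NA = missing visit). Visit
# covariates default to constants so intercept-only detection gives one p.
make_count_data <- function(y, minutes = NULL, day = NULL, observer = NULL,
                            sites = NULL) {
  idx <- which(!is.na(y), arr.ind = TRUE)
  ids <- sprintf("S%03d", seq_len(nrow(y)))
  long <- tibble::tibble(
    point_id = ids[idx[, 1]],
    visit = idx[, 2],
    count = y[idx],
    minutes = if (is.null(minutes)) 400 else minutes[idx],
    day = if (is.null(day)) 100 else day[idx],
    observer = if (is.null(observer)) "obs1" else observer[idx]
  )
  sites <- sites %||% tibble::tibble(point_id = ids)
  if (!"point_id" %in% names(sites)) sites$point_id <- ids
  count_data(long, sites)
}

# Z-score a matrix's observed cells the way the fitter scales numeric
# detection covariates (used when an oracle needs the same design).
zscore_cells <- function(m, y) {
  obs <- which(!is.na(y))
  v <- m[obs]
  z <- matrix(NA_real_, nrow(m), ncol(m))
  s <- sd(v)
  z[obs] <- if (is.na(s) || s == 0) 0 else (v - mean(v)) / s
  z
}

# Minimal hand-built model objects for unit tests of downstream operations.
fake_lapse <- function(intercept, slope, elev_range = c(1000, 2000),
                       response = "night_mean") {
  structure(list(response = response, intercept = intercept, slope = slope,
                 r = -1, r_defined = TRUE, r2 = 1, n = 3, sigma = 0,
                 elev_range = elev_range),
            class = "lapse_model")
}

fake_profile <- function(intercept, slope, threshold = 2,
                         elev_range = c(1200, 2200)) {
  structure(list(species = NULL, intercept = intercept, slope = slope,
                 threshold = threshold, n = 3, elev_range = elev_range,
                 by_logger = tibble::tibble()),
            class = "cost_profile")
}
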