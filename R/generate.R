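# Synthetic field-study generators. Every generator takes an explicit integer
# seed (no reliance on global RNG state) and is bit-reproducible given
# (truth, seed).

# Diel temperature shape in [-1, 1]: minimum at 05:30, maximum at 13:30.
# Asymmetric single cycle built from two half-cosines (8 h rising limb,
# 16 h falling limb), continuous everywhere.
diel_shape <- function(hours) {
  t <- hours %% 24
  tt <- ifelse(t < 5.5, t + 24, t)  # fold early morning onto the falling limb
  ifelse(tt <= 13.5,
         -cos(pi * (tt - 5.5) / 8),
         cos(pi * (tt - 13.5) / 16))
}

#' Simulate temperature-logger time series along the elevational gradient
#'
#' Places loggers at evenly spaced elevations and records temperature every
#' 30 minutes for `days` days. The expected reading at elevation `e` and
#' clock time `t` is `lapse_intercept + lapse_slope * e +
#' diel_amplitude * h(t)` where `h` is a diel cycle with minimum at 05:30
#' and maximum at 13:30 (approximate sunrise and early afternoon), plus
#' Gaussian noise with sd `logger_noise_sd`.
#'
#' @param truth An [elev_truth()] object.
#' @param n_loggers Number of loggers (>= 2).
#' @param elevation_range Ordered pair of elevations in metres.
#' @param days Number of whole days recorded (>= 1); each day contributes 48
#'   readings per logger starting at 00:00 UTC.
#' @param seed Integer seed; defaults to `truth$seed`.
#' @param start_date First calendar date of the series.
#' @return A tibble with columns `logger_id`, `elevation`, `timestamp`
#'   (POSIXct, UTC) and `temp_c`.
#' @export
#' @examples
#' tr <- elev_truth(logger_noise_sd = 0, diel_amplitude = 0)
#' lg <- generate_loggers(tr, n_loggers = 2, elevation_range = c(1000, 2000), days = 1)
#' nrow(lg)  # 2 loggers x 48 readings
generate_loggers <- function(truth, n_loggers, elevation_range, days,
                             seed = truth$seed, start_date = "2023-03-01") {
  stopifnot(inherits(truth, "elev_truth"))
  n_loggers <- check_count(n_loggers, "n_loggers", min = 2)
  days <- check_count(days, "days", min = 1)
  elevation_range <- check_range(elevation_range, "elevation_range")

  elevs <- seq(elevation_range[1], elevation_range[2], length.out = n_loggers)
  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  times <- t0 + seq(0, days * 24 * 3600 - 1800, by = 1800)
  hours <- clock_hours(times)
  base_cycle <- truth$diel_amplitude * diel_shape(hours)

  withr::with_seed(seed, {
    purrr::map(seq_len(n_loggers), function(i) {
      mu <- truth$lapse_intercept + truth$lapse_slope * elevs[i] + base_cycle
      tibble(
        logger_id = sprintf("L%02d", i),
        elevation = elevs[i],
        timestamp = times,
        temp_c = mu + rnorm(length(times), 0, truth$logger_noise_sd)
      )
    }) |> purrr::list_rbind()
  })
}

# The five respirometry chamber-temperature bands (deg C).
resp_bands <- function() {
  matrix(c(5, 10, 11, 16, 17, 22, 23, 28, 29, 34),
         ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("lo", "hi")))
}

#' Simulate respirometry measurements for one species
#'
#' Each bird receives 1-4 chamber-temperature treatments in one night, drawn
#' uniformly within temperature bands (5-10, 11-16, 17-22, 23-28, 29-34 deg C)
#' chosen at random without replacement per bird. The measured metabolic rate
#' is the true piecewise (broken-stick) response plus Gaussian noise; a flat
#' truth yields `bmr` plus noise at every temperature.
#'
#' @param truth_model A [thermo_truth()] object.
#' @param n_birds Number of birds (>= 1).
#' @param treatments_per_bird Either a single count in 1..4 or a range
#'   `c(lo, hi)` from which each bird's number of treatments is drawn
#'   uniformly.
#' @param noise_sd Gaussian measurement noise sd in power units (>= 0).
#' @param species Species label carried into the output.
#' @param seed Integer seed.
#' @return A tibble with columns `bird_id`, `species`, `chamber_temp_c`,
#'   `metabolic_rate`.
#' @export
generate_respirometry <- function(truth_model, n_birds,
                                  treatments_per_bird = c(1, 4),
                                  noise_sd = 0.02, species = "species",
                                  seed = 1L) {
  stopifnot(inherits(truth_model, "thermo_truth"))
  n_birds <- check_count(n_birds, "n_birds", min = 1)
  if (noise_sd < 0) {
    abort("`noise_sd` must be >= 0.", class = "elevrange_input_error")
  }
  tpb <- as.integer(treatments_per_bird)
  if (length(tpb) == 1) tpb <- c(tpb, tpb)
  if (tpb[1] < 1 || tpb[2] > 4 || tpb[1] > tpb[2]) {
    abort("`treatments_per_bird` must lie within 1..4.",
          class = "elevrange_input_error")
  }
  bands <- resp_bands()
  withr::with_seed(seed, {
    purrr::map(seq_len(n_birds), function(b) {
      k <- if (tpb[1] == tpb[2]) tpb[1] else sample(tpb[1]:tpb[2], 1)
      chosen <- sample(nrow(bands), k)  # bands without replacement per bird
      temps <- runif(k, bands[chosen, "lo"], bands[chosen, "hi"])
      tibble(
        bird_id = sprintf("B%03d", b),
        species = species,
        chamber_temp_c = temps,
        metabolic_rate = true_metabolic_rate(truth_model, temps) +
          rnorm(k, 0, noise_sd)
      )
    }) |> purrr::list_rbind()
  })
}

#' Simulate survey points along the gradient
#'
#' Survey points uniformly cover the elevational gradient; horizontal
#' coordinates place them on a planimetric slope (elevation decreasing
#' downhill in `y`) with lateral scatter in `x`, so distances to territory
#' centroids are meaningful.
#'
#' @param n_points Number of points.
#' @param elevation_range Ordered elevation pair (m).
#' @param x_extent Lateral extent (m) over which points scatter.
#' @param seed Integer seed.
#' @return A tibble with `point_id`, `elevation`, `x`, `y` (metres).
#' @export
simulate_points <- function(n_points = 83, elevation_range = c(1200, 2200),
                            x_extent = 4000, seed = 1L) {
  n_points <- check_count(n_points, "n_points", min = 1)
  elevation_range <- check_range(elevation_range, "elevation_range")
  elevs <- seq(elevation_range[1], elevation_range[2], length.out = n_points)
  withr::with_seed(seed, {
    tibble(
      point_id = sprintf("P%03d", seq_len(n_points)),
      elevation = elevs,
      x = runif(n_points, 0, x_extent),
      y = (2600 - elevs) / 0.15  # 15% mean grade maps elevation to downslope distance
    )
  })
}

#' Simulate a repeated point-count survey (zero-inflated Poisson N-mixture)
#'
#' Latent site abundance is zero-inflated Poisson: with probability `psi` a
#' site is structurally unoccupied (N = 0), otherwise `N_i ~ Poisson(lambda_i)`
#' with `log lambda_i` a linear predictor of the site covariates. Each visit's
#' count is a binomial thinning `y_ij ~ Binomial(N_i, p_ij)` with
#' `logit p_ij` a linear predictor of visit covariates: z-scored minutes since
#' midnight, z-scored ordinal day, and observer (categorical, four levels).
#' Sites receive a ragged 1-7 visits; unvisited cells are missing.
#'
#' @param truth An [elev_truth()] object supplying `psi` and detection
#'   coefficients.
#' @param points Tibble of survey points with `point_id` and `elevation`.
#' @param visits_per_point Range `c(lo, hi)` of visits per point, drawn
#'   uniformly, or a single count.
#' @param site_covariates Tibble keyed by `point_id` containing every
#'   covariate named by the abundance coefficients.
#' @param species Which species' abundance coefficients in `truth$abundance`
#'   to use; defaults to the first.
#' @param seed Integer seed.
#' @return A [count_data] object; attributes `latent_n`, `lambda` and
#'   `p_matrix` carry the simulation truth for testing.
#' @export
generate_survey <- function(truth, points, visits_per_point = c(1, 7),
                            site_covariates, species = NULL, seed = truth$seed) {
  stopifnot(inherits(truth, "elev_truth"))
  species <- species %||% names(truth$abundance)[1]
  coefs <- truth$abundance[[species]]
  if (is.null(coefs)) {
    abort(sprintf("No abundance coefficients in truth for species '%s'.", species),
          class = "elevrange_input_error")
  }
  vp <- as.integer(visits_per_point)
  if (length(vp) == 1) vp <- c(vp, vp)
  stopifnot(vp[1] >= 1, vp[1] <= vp[2])

  missing_pts <- setdiff(points$point_id, site_covariates$point_id)
  if (length(missing_pts) > 0) {
    abort(paste0("Site covariates missing for points: ",
                 paste(head(missing_pts, 5), collapse = ", ")),
          class = "elevrange_input_error")
  }
  covs <- site_covariates[match(points$point_id, site_covariates$point_id), ]
  terms_needed <- setdiff(names(coefs), "(Intercept)")
  if (!all(terms_needed %in% names(covs))) {
    abort(paste0("Abundance coefficients name covariates absent from the site table: ",
                 paste(setdiff(terms_needed, names(covs)), collapse = ", ")),
          class = "elevrange_input_error")
  }

  n <- nrow(points)
  X <- cbind("(Intercept)" = 1,
             as.matrix(covs[terms_needed]))
  lambda <- exp(drop(X %*% coefs[c("(Intercept)", terms_needed)]))
  det <- truth$detection

  withr::with_seed(seed, {
    z <- runif(n) < truth$psi
    N <- ifelse(z, 0L, rpois(n, lambda))
    J <- if (vp[1] == vp[2]) rep(vp[1], n) else sample(vp[1]:vp[2], n, replace = TRUE)

    long <- purrr::map(seq_len(n), function(i) {
      tibble(
        point_id = points$point_id[i],
        visit = seq_len(J[i]),
        minutes = runif(J[i], 315, 540),          # surveys between 05:15 and 09:00
        day = round(runif(J[i], 60, 150)),        # ordinal day within the season
        observer = sample(sprintf("obs%d", 1:4), J[i], replace = TRUE)
      )
    }) |> purrr::list_rbind()

    # detection linear predictor on sample z-scores of the numeric covariates
    mz <- as.numeric(scale(long$minutes))
    dz <- if (sd(long$day) > 0) as.numeric(scale(long$day)) else rep(0, nrow(long))
    obs_eff <- c(obs1 = 0, obs2 = unname(det["observer2"]),
                 obs3 = unname(det["observer3"]), obs4 = unname(det["observer4"]))
    eta <- det[["(Intercept)"]] + det[["minutes"]] * mz + det[["day"]] * dz +
      obs_eff[long$observer]
    p <- plogis(eta)

    Ni <- N[match(long$point_id, points$point_id)]
    long$count <- rbinom(nrow(long), Ni, p)
    # degenerate detection limits: p exactly 0 or 1
    long$count[p == 1] <- Ni[p == 1]
    long$count[p == 0] <- 0L

    cd <- count_data(long, covs)
    attr(cd, "latent_n") <- N
    attr(cd, "lambda") <- lambda
    attr(cd, "p_matrix") <- p
    attr(cd, "species") <- species
    cd
  })
}

#' Simulate habitat plots with elevation-structured gradients
#'
#' Per plot: tree stems whose expected cumulative-diameter share of tree
#' ferns rises logistically with elevation (broadleaf and palms falling in
#' step); 40 touch-pole placements with section counts in 0..6, understorey
#' thinning upslope; and 5 quadrats of leaf-litter depth and soil impact
#' depth that are positively correlated between plots.
#'
#' @param truth An [elev_truth()] object (habitat block used).
#' @param points Tibble with `point_id` and `elevation`.
#' @param seed Integer seed.
#' @return An object of class `habitat_plots`: a list of tibbles `stems`
#'   (`point_id`, `type`, `diameter_cm`), `touches` (`point_id`, `placement`,
#'   `touches`) and `quadrats` (`point_id`, `quadrat`, `litter_mm`,
#'   `soil_mm`).
#' @export
generate_habitat <- function(truth, points, seed = truth$seed) {
  stopifnot(inherits(truth, "elev_truth"))
  if (nrow(points) == 0) {
    abort("`points` must be non-empty.", class = "elevrange_input_error")
  }
  hb <- truth$habitat
  dbh <- c(broadleaf = hb$dbh_broadleaf, tree_fern = hb$dbh_fern, palm = hb$dbh_palm)

  withr::with_seed(seed, {
    out <- purrr::map(seq_len(nrow(points)), function(i) {
      e <- points$elevation[i]
      pid <- points$point_id[i]

      # target cumulative-diameter shares
      s_fern <- plogis((e - hb$fern_mid) / hb$fern_scale)
      shares <- c(broadleaf = 0.75 * (1 - s_fern), tree_fern = s_fern,
                  palm = 0.25 * (1 - s_fern))
      # stem-count probabilities chosen so E[diameter share] = target share
      w <- shares / dbh
      n_stems <- rpois(1, hb$stem_rate)
      stems <- if (n_stems > 0 && sum(w) > 0) {
        type_n <- drop(rmultinom(1, n_stems, w / sum(w)))
        type <- rep(names(dbh), type_n)
        tibble(point_id = pid, type = type,
               diameter_cm = rlnorm(n_stems, log(dbh[type]) - 0.3^2 / 2, 0.3))
      } else {
        tibble(point_id = character(), type = character(), diameter_cm = numeric())
      }

      p_touch <- plogis((hb$touch_mid - e) / hb$touch_scale)
      touches <- tibble(point_id = pid, placement = 1:40,
                        touches = rbinom(40, 6, p_touch))

      # correlated plot effect shared by litter and soil, quadrat noise on top
      sig <- hb$floor_sd
      b_l <- rnorm(1, 0, sig[["litter"]])
      b_s <- rnorm(1, hb$floor_cor * sig[["soil"]] / sig[["litter"]] * b_l,
                   sig[["soil"]] * sqrt(1 - hb$floor_cor^2))
      quadrats <- tibble(
        point_id = pid, quadrat = 1:5,
        litter_mm = hb$litter_mean + b_l + rnorm(5, 0, hb$quadrat_sd[["litter"]]),
        soil_mm = hb$soil_mean + b_s + rnorm(5, 0, hb$quadrat_sd[["soil"]])
      )
      list(stems = stems, touches = touches, quadrats = quadrats)
    })
    structure(
      list(stems = purrr::list_rbind(purrr::map(out, "stems")),
           touches = purrr::list_rbind(purrr::map(out, "touches")),
           quadrats = purrr::list_rbind(purrr::map(out, "quadrats")),
           points = points),
      class = "habitat_plots"
    )
  })
}

#' Simulate parapatric territory mosaics for the two congeners
#'
#' Each ridge receives a jittered contact elevation; territories of the
#' lower-elevation species sit strictly below it and those of the
#' higher-elevation species strictly above, so the pair is elevationally
#' parapatric on every ridge while ridge-to-ridge jitter lets their pooled
#' elevational ranges overlap at the whole-site scale.
#'
#' @param truth An [elev_truth()] object (`contact_elevation`,
#'   `ridge_jitter_sd`).
#' @param ridges Number of ridges (>= 1).
#' @param territories_per_ridge Territories per species per ridge.
#' @param species Length-2 character: the lower- then the higher-elevation
#'   species.
#' @param seed Integer seed.
#' @return A tibble of class `territory_map` with `species`, `ridge`,
#'   `territory_id`, `x`, `y`, `elevation`.
#' @export
generate_territories <- function(truth, ridges, territories_per_ridge,
                                 species = c("C_mexicanus", "C_frantzii"),
                                 seed = truth$seed) {
  stopifnot(inherits(truth, "elev_truth"), length(species) == 2)
  ridges <- check_count(ridges, "ridges", min = 1)
  territories_per_ridge <- check_count(territories_per_ridge,
                                       "territories_per_ridge", min = 1)

  withr::with_seed(seed, {
    res <- purrr::map(seq_len(ridges), function(r) {
      contact_r <- truth$contact_elevation + rnorm(1, 0, truth$ridge_jitter_sd)
      x0 <- (r - 1) * 800
      below <- contact_r - runif(territories_per_ridge, 30, 400)
      above <- contact_r + runif(territories_per_ridge, 30, 400)
      elev <- c(below, above)
      tibble(
        species = rep(species, each = territories_per_ridge),
        ridge = r,
        territory_id = sprintf("R%02d_%s_%02d", r,
                               rep(c("lo", "hi"), each = territories_per_ridge),
                               rep(seq_len(territories_per_ridge), 2)),
        x = x0 + runif(2 * territories_per_ridge, -250, 250),
        y = (2600 - elev) / 0.15,
        elevation = elev,
        contact_elevation = contact_r
      )
    }) |> purrr::list_rbind()
    class(res) <- c("territory_map", class(res))
    res
  })
}
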