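# Broken-stick (Scholander-Irving) metabolic models fitted to respirometry
# data, with a flat no-cost alternative selected by AICc.

band_breaks <- c(-Inf, 10.5, 16.5, 22.5, 28.5, Inf)

# Gaussian log-likelihood at the MLE of the residual variance.
loglik_gauss <- function(sse, n) {
  if (sse <= 0) return(Inf)  # perfect fit
  -n / 2 * (log(2 * pi * sse / n) + 1)
}

aicc_value <- function(loglik, k, n) {
  if (n <= k + 1) {
    warn(sprintf("AICc undefined for n = %d, k = %d (n <= k + 1); reporting Inf.",
                 n, k),
         class = "elevrange_aicc_undefined")
    return(Inf)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a thermoregulation model to respirometry measurements
#'
#' Fits the broken-stick metabolic response -- rate = BMR for chamber
#' temperatures at or above the lower critical temperature `T_lc`, rising
#' linearly below it with slope `C_min` (minimum thermal conductance) --
#' with continuity enforced at the breakpoint. The breakpoint is profiled
#' over a 0.1 deg C grid spanning the interior of the observed temperatures
#' (excluding the outermost two points on each side); for each candidate
#' breakpoint, (BMR, C_min) are estimated by conditional least squares with
#' `C_min` constrained non-negative. The alternative is a flat model (rate =
#' BMR everywhere, i.e. no thermoregulatory cost in the tested range). The
#' returned variant is the one with the lower AICc (broken-stick counts 4
#' parameters including the residual variance, flat counts 2); ties and
#' non-positive fitted slopes go to the flat variant.
#'
#' @param data Tibble with columns `chamber_temp_c` and `metabolic_rate`
#'   (and optionally `species`).
#' @param species Optional species label; if `data` has a `species` column
#'   the rows are filtered to it.
#' @param grid_step Breakpoint grid resolution, deg C.
#' @return An object of class `thermo_model`: `species`, `variant`
#'   (`"broken_stick"` or `"flat"`), `bmr`, `t_lc`, `c_min`, `sigma`, `n`,
#'   `aicc`, `aicc_broken`, `aicc_flat`, the SSE `profile` over the grid and
#'   the observed `temp_range`.
#' @export
#' @examples
#' tr <- thermo_truth(bmr = 0.5, t_lc = 18, c_min = 0.02)
#' d <- generate_respirometry(tr, n_birds = 8, treatments_per_bird = 3,
#'                            noise_sd = 0, seed = 2)
#' fit <- fit_thermoregulation(d)
#' fit$variant
fit_thermoregulation <- function(data, species = NULL, grid_step = 0.1) {
  if (!is.null(species) && "species" %in% names(data)) {
    data <- filter(data, .data$species == !!species)
  }
  temp <- data$chamber_temp_c
  rate <- data$metabolic_rate
  n <- length(temp)
  if (n < 6) {
    abort("Need >= 6 respirometry measurements.", class = "elevrange_design_error")
  }
  bands <- cut(temp, band_breaks)
  if (dplyr::n_distinct(bands) < 3) {
    abort("Measurements must span >= 3 temperature bands.",
          class = "elevrange_design_error")
  }
  if (dplyr::n_distinct(temp) == 1) {
    abort("All chamber temperatures identical; breakpoint not estimable.",
          class = "elevrange_design_error")
  }

  ts <- sort(temp)
  lo <- ts[3]
  hi <- ts[n - 2]
  mean_rate <- mean(rate)
  syy <- sum((rate - mean_rate)^2)
  sse_flat <- syy

  grid <- NULL
  if (lo < hi) {
    lo10 <- ceiling(lo / grid_step - 1e-9)
    hi10 <- floor(hi / grid_step + 1e-9)
    if (lo10 <= hi10) grid <- (lo10:hi10) * grid_step
  }
  if (is.null(grid)) {
    abort("Interior temperature range too narrow to profile a breakpoint.",
          class = "elevrange_design_error")
  }

  prof <- purrr::map(grid, function(cand) {
    x <- pmax(cand - temp, 0)
    sxx <- sum((x - mean(x))^2)
    if (sxx == 0) {
      return(tibble(t_lc = cand, bmr = mean_rate, c_min = 0, sse = sse_flat))
    }
    sxy <- sum((x - mean(x)) * (rate - mean_rate))
    b <- sxy / sxx
    if (b < 0) {
      tibble(t_lc = cand, bmr = mean_rate, c_min = 0, sse = sse_flat)
    } else {
      tibble(t_lc = cand, bmr = mean_rate - b * mean(x), c_min = b,
             sse = syy - b * sxy)
    }
  }) |> purrr::list_rbind()

  best <- prof[which.min(prof$sse), ]
  ll_broken <- loglik_gauss(best$sse, n)
  ll_flat <- loglik_gauss(sse_flat, n)
  aicc_broken <- if (is.infinite(ll_broken)) -Inf else aicc_value(ll_broken, 4, n)
  aicc_flat <- if (is.infinite(ll_flat)) -Inf else aicc_value(ll_flat, 2, n)

  choose_flat <- best$c_min <= 0 ||
    aicc_flat <= aicc_broken + 1e-9  # ties favour the simpler model
  if (choose_flat) {
    structure(
      list(species = species %||% data$species[1] %||% NA_character_,
           variant = "flat", bmr = mean_rate, t_lc = NULL, c_min = NULL,
           sigma = sqrt(sse_flat / n), n = n,
           aicc = aicc_flat, aicc_broken = aicc_broken, aicc_flat = aicc_flat,
           profile = prof, temp_range = range(temp)),
      class = "thermo_model"
    )
  } else {
    structure(
      list(species = species %||% data$species[1] %||% NA_character_,
           variant = "broken_stick", bmr = best$bmr, t_lc = best$t_lc,
           c_min = best$c_min,
           sigma = sqrt(best$sse / n), n = n,
           aicc = aicc_broken, aicc_broken = aicc_broken, aicc_flat = aicc_flat,
           profile = prof, temp_range = range(temp)),
      class = "thermo_model"
    )
  }
}

#' Thermoregulatory cost as a multiple of BMR
#'
#' For a flat model the cost is 1 at every temperature (no thermoregulatory
#' cost detected in the tested range). For a broken-stick model the cost is
#' 1 at or above `T_lc` and `(BMR + C_min * (T_lc - T)) / BMR` below it:
#' always >= 1 and continuous in `T`.
#'
#' @param model A `thermo_model` (from [fit_thermoregulation()]) or a
#'   [thermo_truth()].
#' @param temp Numeric vector of temperatures, deg C.
#' @return Numeric vector of unitless cost multiples.
#' @export
#' @examples
#' m <- thermo_truth(bmr = 0.5, t_lc = 18, c_min = 0.02)
#' cost_multiple(m, c(8, 18, 30))  # 1.4, 1, 1
cost_multiple <- function(model, temp) {
  stopifnot(inherits(model, c("thermo_model", "thermo_truth")))
  if (model$variant == "flat") {
    rep(1, length(temp))
  } else {
    1 + model$c_min * pmax(model$t_lc - temp, 0) / model$bmr
  }
}

#' @export
print.thermo_model <- function(x, ...) {
  cat(sprintf("<thermo_model: %s (%s)>\n",
              x$species %||% "?", x$variant))
  if (x$variant == "broken_stick") {
    cat(sprintf("  BMR = %.4g, T_lc = %.1f degC, C_min = %.4g per degC; n = %d\n",
                x$bmr, x$t_lc, x$c_min, x$n))
  } else {
    cat(sprintf("  BMR = %.4g (no cost detected in [%.1f, %.1f] degC); n = %d\n",
                x$bmr, x$temp_range[1], x$temp_range[2], x$n))
  }
  cat(sprintf("  AICc: broken-stick %.2f, flat %.2f\n", x$aicc_broken, x$aicc_flat))
  invisible(x)
}

#' @export
tidy.thermo_model <- function(x, ...) {
  if (x$variant == "broken_stick") {
    tibble(term = c("bmr", "t_lc", "c_min"),
           estimate = c(x$bmr, x$t_lc, x$c_min))
  } else {
    tibble(term = "bmr", estimate = x$bmr)
  }
}

#' @export
glance.thermo_model <- function(x, ...) {
  tibble(species = x$species %||% NA_character_, variant = x$variant,
         bmr = x$bmr, t_lc = x$t_lc %||% NA_real_, c_min = x$c_min %||% NA_real_,
         sigma = x$sigma, n = x$n, aicc = x$aicc,
         aicc_broken = x$aicc_broken, aicc_flat = x$aicc_flat)
}
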