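# Fundamental physiological niche: project nightly thermoregulatory costs
# onto elevation and invert the sustainability threshold (default 2 x BMR)
# into a thermal-ceiling elevation.

#' Season-mean nightly thermoregulatory cost at each logger
#'
#' For each logger, evaluates [cost_multiple()] at every night-time reading
#' (the complement of the day window, i.e. sunset to sunrise), averages
#' within each complete night, then averages those nightly means over the
#' season. Daytime readings never enter; incomplete first/last nights are
#' dropped, and loggers with no complete nights are omitted with a warning.
#'
#' @param model A `thermo_model` or [thermo_truth()].
#' @param loggers Logger series tibble ([generate_loggers()] format).
#' @param day_window Clock-time pair delimiting the day; the night is its
#'   complement.
#' @return A tibble with `logger_id`, `elevation`, `mean_cost`, `n_nights`.
#' @export
nightly_cost_by_logger <- function(model, loggers,
                                   day_window = c("05:30", "18:30")) {
  stopifnot(inherits(model, c("thermo_model", "thermo_truth")))
  parts <- partition_day_night(loggers, day_window)
  nights <- parts |>
    filter(!.data$.is_day) |>
    group_by(.data$logger_id, .data$elevation, night = .data$.night_date) |>
    summarise(cost = mean(cost_multiple(model, .data$temp_c)),
              complete = any(.data$.segment == "evening") &&
                any(.data$.segment == "morning"),
              .groups = "drop") |>
    filter(.data$complete)

  out <- nights |>
    group_by(.data$logger_id, .data$elevation) |>
    summarise(mean_cost = mean(.data$cost), n_nights = dplyr::n(),
              .groups = "drop")

  omitted <- setdiff(unique(loggers$logger_id), out$logger_id)
  if (length(omitted) > 0) {
    warn(paste0("Loggers with no complete nights omitted: ",
                paste(omitted, collapse = ", ")),
         class = "elevrange_partial_days")
  }
  out
}

#' Fit the cost-versus-elevation line
#'
#' Ordinary least squares of the season-mean nightly cost multiple on logger
#' elevation, mirroring the lapse-model fit for temperature. The line is
#' linear even though the exact composition of a broken-stick cost with a
#' linear lapse is piecewise linear in elevation; the kink is absorbed by
#' OLS (see [piecewise_cost()] for the exact alternative).
#'
#' @param costs Tibble from [nightly_cost_by_logger()].
#' @param threshold Sustainability threshold in multiples of BMR (> 1);
#'   default 2, the conservative upper limit of sustainable thermoregulatory
#'   expenditure for tropical birds.
#' @param species Optional species label.
#' @return An object of class `cost_profile`: `intercept` (unitless),
#'   `slope` (per m), `threshold`, `n`, `elev_range`, per-logger inputs in
#'   `by_logger`.
#' @export
fit_cost_elevation <- function(costs, threshold = 2, species = NULL) {
  if (threshold <= 1) {
    abort("`threshold` must exceed 1 (a cost of 1 is BMR itself).",
          class = "elevrange_input_error")
  }
  if (dplyr::n_distinct(costs$elevation) < 3) {
    abort("Need >= 3 distinct logger elevations.", class = "elevrange_design_error")
  }
  fit <- lm(mean_cost ~ elevation, data = costs)
  cf <- coef(fit)
  flat <- sd(costs$mean_cost) == 0
  structure(
    list(species = species,
         intercept = if (flat) costs$mean_cost[1] else unname(cf[1]),
         slope = if (flat) 0 else unname(cf[2]),
         threshold = threshold,
         n = nrow(costs),
         elev_range = range(costs$elevation),
         by_logger = costs),
    class = "cost_profile"
  )
}

#' Predict the mean nightly cost multiple at an elevation
#'
#' @param profile A [fit_cost_elevation()] object.
#' @param elevation Numeric vector of elevations (m).
#' @return A tibble with `elevation`, `cost`, `extrapolated`.
#' @export
predict_cost <- function(profile, elevation) {
  stopifnot(inherits(profile, "cost_profile"))
  tibble(
    elevation = elevation,
    cost = profile$intercept + profile$slope * elevation,
    extrapolated = elevation < profile$elev_range[1] |
      elevation > profile$elev_range[2]
  )
}

#' Exact piecewise cost prediction (alternative to the fitted line)
#'
#' Composes the lapse-model temperature prediction with the thermoregulation
#' model directly: `cost_multiple(model, predict_temperature(lapse, e))`.
#' This is the exact (piecewise-linear in elevation) prediction of the cost
#' at the season-mean night temperature; the default analysis instead fits a
#' straight line through per-logger season-mean costs.
#'
#' @param model A `thermo_model` or [thermo_truth()].
#' @param lapse A `lapse_model` (typically fitted to `night_mean`).
#' @param elevation Numeric vector of elevations (m).
#' @return A tibble with `elevation`, `temp_c`, `cost`, `extrapolated`.
#' @export
piecewise_cost <- function(model, lapse, elevation) {
  pt <- predict_temperature(lapse, elevation)
  pt$cost <- cost_multiple(model, pt$temp_c)
  pt[, c("elevation", "temp_c", "cost", "extrapolated")]
}

#' Thermal-ceiling elevation
#'
#' Inverts the fitted cost line at the sustainability threshold: the
#' elevation where the projected mean nightly cost reaches `threshold`
#' multiples of BMR. No ceiling exists when the cost does not increase with
#' elevation (slope <= 0) or when the solution falls below the fitted
#' elevation range; a ceiling above the fitted range is returned but flagged
#' as extrapolated.
#'
#' @param profile A [fit_cost_elevation()] object.
#' @param threshold Overrides the profile's threshold if given (> 1).
#' @return A one-row tibble: `ceiling_m` (NA when none), `extrapolated`,
#'   `reason` (`"ok"`, `"no_positive_slope"` or `"below_fitted_range"`).
#' @export
#' @examples
#' pr <- structure(list(intercept = 0.52, slope = 4e-4, threshold = 2,
#'                      elev_range = c(1200, 2200)), class = "cost_profile")
#' thermal_ceiling(pr)$ceiling_m  # 3700, extrapolated
thermal_ceiling <- function(profile, threshold = NULL) {
  stopifnot(inherits(profile, "cost_profile"))
  thr <- threshold %||% profile$threshold
  if (thr <= 1) {
    abort("`threshold` must exceed 1.", class = "elevrange_input_error")
  }
  if (profile$slope <= 0) {
    return(tibble(ceiling_m = NA_real_, extrapolated = NA,
                  reason = "no_positive_slope"))
  }
  e <- (thr - profile$intercept) / profile$slope
  if (e < profile$elev_range[1]) {
    return(tibble(ceiling_m = NA_real_, extrapolated = NA,
                  reason = "below_fitted_range"))
  }
  tibble(ceiling_m = e, extrapolated = e > profile$elev_range[2], reason = "ok")
}

#' @export
print.cost_profile <- function(x, ...) {
  cat(sprintf("<cost_profile%s>\n",
              if (!is.null(x$species)) paste0(": ", x$species) else ""))
  cat(sprintf("  cost = %.4f %+.3g * elevation; threshold %.2g x BMR; %d loggers\n",
              x$intercept, x$slope, x$threshold, x$n))
  invisible(x)
}

#' @export
glance.cost_profile <- function(x, ...) {
  ceil <- thermal_ceiling(x)
  tibble(species = x$species %||% NA_character_, intercept = x$intercept,
         slope = x$slope, threshold = x$threshold, n = x$n,
         ceiling_m = ceil$ceiling_m, ceiling_extrapolated = ceil$extrapolated)
}

#' Plot a thermal cost profile
#'
#' Per-logger season-mean nightly cost multiples against elevation with the
#' fitted line, a dashed horizontal line at the sustainability threshold,
#' and optionally a bar marking the species' occupied elevational range.
#'
#' @param object A [fit_cost_elevation()] object.
#' @param occupied_range Optional elevation pair marking the occupied range.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cost_profile <- function(object, occupied_range = NULL, ...) {
  p <- ggplot(object$by_logger, aes(x = .data$elevation, y = .data$mean_cost)) +
    geom_point(colour = "grey30") +
    geom_abline(intercept = object$intercept, slope = object$slope,
                colour = "steelblue") +
    geom_hline(yintercept = object$threshold, linetype = "dashed") +
    labs(x = "Elevation (m)",
         y = "Mean nightly thermoregulatory cost (x BMR)",
         title = object$species %||% NULL) +
    theme_minimal()
  if (!is.null(occupied_range)) {
    p <- p + annotate("segment", x = occupied_range[1], xend = occupied_range[2],
                      y = 1, yend = 1, linewidth = 2, colour = "black")
  }
  p
}
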