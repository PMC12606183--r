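# Thermal environment: day/night summaries of logger series and linear
# elevational lapse models.

# Classify readings into day/night and assign each night to the calendar
# date on which it begins (the sunset side).
partition_day_night <- function(series, day_window = c("05:30", "18:30")) {
  w <- parse_clock(day_window)
  if (w[1] >= w[2]) {
    abort("`day_window` must satisfy start < end.", class = "elevrange_input_error")
  }
  hrs <- clock_hours(series$timestamp)
  date <- as.Date(series$timestamp, tz = "UTC")
  is_day <- hrs >= w[1] & hrs < w[2]
  series |>
    mutate(
      .hrs = hrs,
      .date = date,
      .is_day = is_day,
      # night segment: evening (>= sunset, same date) or morning (< sunrise,
      # belongs to the previous date's night)
      .night_date = dplyr::if_else(hrs >= w[2], date, date - 1L),
      .segment = dplyr::case_when(is_day ~ "day",
                                  hrs >= w[2] ~ "evening",
                                  TRUE ~ "morning")
    )
}

#' Summarize logger series into daily day and night statistics
#'
#' For each logger and date, computes the mean, maximum and minimum
#' temperature over readings whose clock time falls inside the day window
#' (default 05:30-18:30, the approximate sunrise-sunset interval), and the
#' mean over the complementary night readings, with each night assigned to
#' the date on which it begins. A night is complete only when it has both
#' evening (post-sunset) and morning (pre-sunrise) readings; the partial
#' first and last nights of a series are therefore dropped, and interior
#' dates missing either partition are omitted with a warning.
#'
#' @param series Logger tibble as produced by [generate_loggers()] (columns
#'   `logger_id`, `elevation`, `timestamp`, `temp_c`).
#' @param day_window Clock-time pair `c(start, end)` as `"HH:MM"` strings or
#'   decimal hours.
#' @return A tibble with `logger_id`, `elevation`, `date`, `day_mean`,
#'   `day_max`, `day_min`, `night_mean`, `n_day`, `n_night`.
#' @export
summarize_days <- function(series, day_window = c("05:30", "18:30")) {
  stopifnot(all(c("logger_id", "timestamp", "temp_c") %in% names(series)))
  parts <- partition_day_night(series, day_window)
  has_elev <- "elevation" %in% names(series)

  day_tbl <- parts |>
    filter(.data$.is_day) |>
    group_by(.data$logger_id, date = .data$.date) |>
    summarise(day_mean = mean(.data$temp_c), day_max = max(.data$temp_c),
              day_min = min(.data$temp_c), n_day = dplyr::n(),
              .groups = "drop")

  night_tbl <- parts |>
    filter(!.data$.is_day) |>
    group_by(.data$logger_id, date = .data$.night_date) |>
    summarise(night_mean = mean(.data$temp_c), n_night = dplyr::n(),
              complete = any(.data$.segment == "evening") &&
                any(.data$.segment == "morning"),
              .groups = "drop") |>
    filter(.data$complete) |>
    select(-"complete")

  out <- inner_join(day_tbl, night_tbl, by = c("logger_id", "date"))

  dropped <- anti_join(day_tbl, out, by = c("logger_id", "date"))
  bounds <- day_tbl |>
    group_by(.data$logger_id) |>
    summarise(.dmin = min(.data$date), .dmax = max(.data$date), .groups = "drop")
  interior <- dropped |>
    left_join(bounds, by = "logger_id") |>
    filter(.data$date != .data$.dmin, .data$date != .data$.dmax)
  if (nrow(interior) > 0) {
    warn(sprintf("%d logger-date(s) omitted: empty day or night partition.",
                 nrow(interior)),
         class = "elevrange_partial_days")
  }
  if (has_elev) {
    elevs <- distinct(series, .data$logger_id, .data$elevation)
    out <- left_join(out, elevs, by = "logger_id") |>
      relocate("elevation", .after = "logger_id")
  }
  out
}

#' Fit a linear elevational lapse model
#'
#' Averages the chosen daily response per logger across the season (one
#' value per logger, avoiding logger-day pseudo-replication) and regresses
#' it on elevation by ordinary least squares, giving the lapse line used to
#' predict temperature at any survey elevation.
#'
#' @param summaries Output of [summarize_days()].
#' @param response One of `"night_mean"`, `"day_mean"`, `"day_max"`,
#'   `"day_min"`.
#' @param elevations Optional tibble `logger_id`, `elevation` (or named
#'   vector); defaults to the `elevation` column of `summaries`.
#' @return An object of class `lapse_model` with fields `response`,
#'   `intercept` (deg C), `slope` (deg C per m), `r` (correlation;
#'   0 with `r_defined = FALSE` for a flat response), `r2`, `n` (loggers),
#'   `sigma`, `elev_range`, and the per-logger means in `by_logger`.
#' @export
fit_lapse_model <- function(summaries,
                            response = c("night_mean", "day_mean",
                                         "day_max", "day_min"),
                            elevations = NULL) {
  response <- match.arg(response)
  if (!is.null(elevations)) {
    if (!is.data.frame(elevations)) {
      elevations <- tibble(logger_id = names(elevations),
                           elevation = as.numeric(elevations))
    }
    summaries <- summaries |>
      select(-dplyr::any_of("elevation")) |>
      inner_join(elevations, by = "logger_id")
  }
  if (!"elevation" %in% names(summaries)) {
    abort("No elevations available: supply `elevations` or include an `elevation` column.",
          class = "elevrange_input_error")
  }
  by_logger <- summaries |>
    group_by(.data$logger_id, .data$elevation) |>
    summarise(value = mean(.data[[response]]), n_days = dplyr::n(),
              .groups = "drop")
  if (dplyr::n_distinct(by_logger$elevation) < 3) {
    abort("Need >= 3 distinct logger elevations to fit a lapse model.",
          class = "elevrange_design_error")
  }
  fit <- lm(value ~ elevation, data = by_logger)
  cf <- coef(fit)
  flat <- sd(by_logger$value) == 0
  r <- if (flat) 0 else cor(by_logger$elevation, by_logger$value)
  structure(
    list(response = response,
         intercept = unname(cf[1]),
         slope = if (flat) 0 else unname(cf[2]),
         r = r, r_defined = !flat, r2 = r^2,
         n = nrow(by_logger),
         sigma = sqrt(sum(fit$residuals^2) / max(1, fit$df.residual)),
         elev_range = range(by_logger$elevation),
         by_logger = by_logger),
    class = "lapse_model"
  )
}

#' Predict temperature at an elevation from a lapse model
#'
#' Affine evaluation `intercept + slope * elevation`. Predictions outside
#' the fitted elevation range are permitted but flagged as extrapolated.
#'
#' @param model A [fit_lapse_model()] object.
#' @param elevation Numeric vector of elevations (m).
#' @return A tibble with `elevation`, `temp_c`, `extrapolated`.
#' @export
#' @examples
#' m <- structure(list(intercept = 25, slope = -0.005,
#'                     elev_range = c(1000, 2000)), class = "lapse_model")
#' predict_temperature(m, 2000)$temp_c  # 15
predict_temperature <- function(model, elevation) {
  stopifnot(inherits(model, "lapse_model"))
  tibble(
    elevation = elevation,
    temp_c = model$intercept + model$slope * elevation,
    extrapolated = elevation < model$elev_range[1] | elevation > model$elev_range[2]
  )
}

#' @export
print.lapse_model <- function(x, ...) {
  cat(sprintf("<lapse_model: %s>\n", x$response))
  cat(sprintf("  T = %.3f %+.3g * elevation (degC, m); r = %s; n = %d loggers\n",
              x$intercept, x$slope,
              if (x$r_defined) sprintf("%.3f", x$r) else "undefined (flat)",
              x$n))
  invisible(x)
}

#' @export
tidy.lapse_model <- function(x, ...) {
  tibble(term = c("(Intercept)", "elevation"),
         estimate = c(x$intercept, x$slope))
}

#' @export
glance.lapse_model <- function(x, ...) {
  tibble(response = x$response, intercept = x$intercept, slope = x$slope,
         r = x$r, r2 = x$r2, sigma = x$sigma, n = x$n)
}
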