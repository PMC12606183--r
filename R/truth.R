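#' Ground-truth parameter set for the synthetic field study
#'
#' Bundles every generative assumption of the synthetic-data module: the
#' linear elevational temperature lapse with a diel cycle, per-species
#' thermoregulation truths (broken-stick or flat), abundance and detection
#' coefficients for the zero-inflated Poisson N-mixture count generator,
#' elevation-structured habitat gradients, and the parapatric territory
#' mosaic of the two congeners. Defaults describe a tropical montane study
#' site spanning roughly 1200-2200 m with four understorey insectivores, one
#' of which (the high-elevation congener) shows no measurable
#' thermoregulatory cost.
#'
#' @param lapse_intercept Sea-level temperature in deg C of the lapse line.
#' @param lapse_slope Lapse rate in deg C per metre; must be negative.
#' @param diel_amplitude Half peak-to-trough amplitude of the diel
#'   temperature cycle, deg C (minimum at 05:30, maximum at 13:30).
#' @param logger_noise_sd Gaussian reading noise sd, deg C.
#' @param thermo Named list of per-species thermoregulation truths built
#'   with [thermo_truth()].
#' @param abundance Named list (one per species) of named coefficient
#'   vectors on the log-abundance scale; names must include `"(Intercept)"`
#'   and otherwise match site-covariate columns supplied to
#'   [generate_survey()].
#' @param detection Named numeric vector of detection coefficients on the
#'   logit scale: intercept, effects of z-scored minutes-since-midnight and
#'   ordinal day, and offsets for observers 2-4.
#' @param psi Zero-inflation probability in `[0, 1)`: extra mass of
#'   structurally unoccupied sites.
#' @param habitat List of habitat-gradient parameters; see Details.
#' @param contact_elevation Mean elevation (m) of the congener contact zone.
#' @param ridge_jitter_sd Ridge-to-ridge sd (m) of the contact elevation.
#' @param seed Default integer seed used by generators when none is given.
#'
#' @details The habitat block has elements `fern_mid`/`fern_scale` (logistic
#' transition of the expected tree-fern share of cumulative diameter, rising
#' with elevation), `stem_rate` (mean stems per plot), mean stem diameters
#' per type (`dbh_broadleaf`, `dbh_fern`, `dbh_palm`, cm),
#' `touch_mid`/`touch_scale` (logistic trend of per-section touch
#' probability, understorey thinning upslope), and the forest-floor block
#' `litter_mean`, `soil_mean` (mm), `floor_sd` (between-plot sd),
#' `floor_cor` (between-plot litter-soil correlation) and `quadrat_sd`
#' (within-plot quadrat noise).
#'
#' @return An object of class `elev_truth` (a validated list).
#' @seealso [generate_loggers()], [generate_survey()], [generate_habitat()],
#'   [generate_territories()], [thermo_truth()]
#' @export
#' @examples
#' tr <- elev_truth()
#' tr$lapse_slope
elev_truth <- function(lapse_intercept = 25,
                       lapse_slope = -0.0052,
                       diel_amplitude = 4,
                       logger_noise_sd = 0.5,
                       thermo = list(
                         C_mexicanus   = thermo_truth(bmr = 0.50, t_lc = 18, c_min = 0.020),
                         C_frantzii    = thermo_truth(bmr = 0.45),
                         H_leucophrys  = thermo_truth(bmr = 0.40, t_lc = 16, c_min = 0.015),
                         A_brunneinucha = thermo_truth(bmr = 0.55, t_lc = 14, c_min = 0.012)
                       ),
                       abundance = list(
                         C_mexicanus   = c("(Intercept)" = 0.7, pct_tree_fern = -0.5, pct_palm = 0.35),
                         C_frantzii    = c("(Intercept)" = -0.4, dist_congener = 1.0, dist_congener_sq = -0.3),
                         H_leucophrys  = c("(Intercept)" = 0.5, thermal_cost = 0.4),
                         A_brunneinucha = c("(Intercept)" = 0.4)
                       ),
                       detection = c("(Intercept)" = 0.5, minutes = -0.4, day = 0,
                                     observer2 = -0.2, observer3 = 0.2, observer4 = 0),
                       psi = 0.3,
                       habitat = list(
                         fern_mid = 1850, fern_scale = 180,
                         stem_rate = 25,
                         dbh_broadleaf = 18, dbh_fern = 9, dbh_palm = 7,
                         touch_mid = 1700, touch_scale = 400,
                         litter_mean = 30, soil_mean = 20,
                         floor_sd = c(litter = 7, soil = 5),
                         floor_cor = 0.6,
                         quadrat_sd = c(litter = 3, soil = 2)
                       ),
                       contact_elevation = 1900,
                       ridge_jitter_sd = 60,
                       seed = 1L) {
  if (!is.finite(lapse_slope) || lapse_slope >= 0) {
    abort("`lapse_slope` must be negative (temperature falls with elevation).",
          class = "elevrange_input_error")
  }
  check_nonneg(diel_amplitude, "diel_amplitude")
  check_nonneg(logger_noise_sd, "logger_noise_sd")
  if (!is.finite(psi) || psi < 0 || psi >= 1) {
    abort("`psi` must lie in [0, 1).", class = "elevrange_input_error")
  }
  check_nonneg(ridge_jitter_sd, "ridge_jitter_sd")
  stopifnot(is.list(thermo), is.list(abundance))
  structure(
    list(lapse_intercept = lapse_intercept, lapse_slope = lapse_slope,
         diel_amplitude = diel_amplitude, logger_noise_sd = logger_noise_sd,
         thermo = thermo, abundance = abundance, detection = detection,
         psi = psi, habitat = habitat,
         contact_elevation = contact_elevation,
         ridge_jitter_sd = ridge_jitter_sd,
         seed = as.integer(seed)),
    class = "elev_truth"
  )
}

#' True thermoregulation parameters for one species
#'
#' The generative counterpart of [fit_thermoregulation()]: a Scholander-Irving
#' broken-stick response (metabolic rate equals BMR at or above the lower
#' critical temperature `t_lc` and rises linearly below it with slope
#' `c_min`), or a flat no-cost variant when `t_lc` is `NULL`.
#'
#' @param bmr Basal metabolic rate, in arbitrary power units (> 0). Cost
#'   multiples are unitless ratios so units cancel downstream.
#' @param t_lc Lower critical temperature, deg C; `NULL` for the flat variant.
#' @param c_min Minimum thermal conductance, power units per deg C (> 0 when
#'   `t_lc` is given).
#' @return An object of class `thermo_truth`.
#' @export
#' @examples
#' thermo_truth(bmr = 0.5, t_lc = 18, c_min = 0.02)
#' thermo_truth(bmr = 0.45)  # flat: no thermoregulatory cost
thermo_truth <- function(bmr, t_lc = NULL, c_min = NULL) {
  if (!is.finite(bmr) || bmr <= 0) {
    abort("`bmr` must be > 0.", class = "elevrange_input_error")
  }
  flat <- is.null(t_lc)
  if (!flat) {
    if (is.null(c_min) || !is.finite(c_min) || c_min <= 0) {
      abort("`c_min` must be > 0 for a broken-stick truth.",
            class = "elevrange_input_error")
    }
  }
  structure(list(variant = if (flat) "flat" else "broken_stick",
                 bmr = bmr, t_lc = t_lc, c_min = c_min),
            class = "thermo_truth")
}

# True metabolic rate at chamber temperature T (vectorized).
true_metabolic_rate <- function(truth, temp) {
  stopifnot(inherits(truth, "thermo_truth"))
  if (truth$variant == "flat") {
    rep(truth$bmr, length(temp))
  } else {
    truth$bmr + truth$c_min * pmax(truth$t_lc - temp, 0)
  }
}

#' @export
print.elev_truth <- function(x, ...) {
  cat("<elev_truth>\n")
  cat(sprintf("  lapse: %.2f degC - %.4g degC/m; diel amplitude %.1f; noise sd %.2f\n",
              x$lapse_intercept, x$lapse_slope, x$diel_amplitude, x$logger_noise_sd))
  cat(sprintf("  species: %s\n", paste(names(x$thermo), collapse = ", ")))
  cat(sprintf("  psi = %.2f; contact %.0f m (ridge sd %.0f m); seed %d\n",
              x$psi, x$contact_elevation, x$ridge_jitter_sd, x$seed))
  invisible(x)
}
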