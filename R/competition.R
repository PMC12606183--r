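# Distance-to-congener covariates and the full-vs-reduced AICc comparison
# testing the interspecific-competition hypothesis.

#' Distance from each survey point to the closest congener territory
#'
#' Minimum Euclidean distance in the horizontal plane (x, y) from each
#' survey point to any territory centroid of the congener. Centroids are
#' used because territory boundaries are not mapped.
#'
#' @param points Tibble with `point_id`, `x`, `y`.
#' @param congener A `territory_map` (or tibble with `x`, `y`), optionally
#'   filtered with `species`.
#' @param species If given and `congener` has a `species` column, only that
#'   species' territories are used.
#' @return A tibble with `point_id`, `distance_m`.
#' @export
#' @examples
#' pts <- tibble::tibble(point_id = "P1", x = 0, y = 0)
#' terr <- tibble::tibble(x = 300, y = 400)
#' distance_to_congener(pts, terr)$distance_m  # 500
distance_to_congener <- function(points, congener, species = NULL) {
  if (!is.null(species) && "species" %in% names(congener)) {
    congener <- filter(congener, .data$species == !!species)
  }
  if (nrow(congener) == 0) {
    abort("Congener territory map is empty.", class = "elevrange_input_error")
  }
  stopifnot(all(c("x", "y") %in% names(points)),
            all(c("x", "y") %in% names(congener)))
  dx <- outer(points$x, congener$x, "-")
  dy <- outer(points$y, congener$y, "-")
  tibble(point_id = points$point_id,
         distance_m = sqrt(apply(dx^2 + dy^2, 1, min)))
}

#' Quadratic competition terms (linked covariate pair)
#'
#' The raw distance and its square, each z-scored, returned as a linked
#' pair (`dist_congener`, `dist_congener_sq`) that abundance models enter
#' or drop together. The quadratic lets abundance respond nonlinearly to
#' proximity to the congener's territories.
#'
#' @param distances Tibble with `point_id`, `distance_m` (>= 0).
#' @return A tibble with `point_id`, `dist_congener`, `dist_congener_sq`;
#'   attribute `linked_pair` names the two columns, attribute `scaling`
#'   their centres and scales.
#' @export
competition_terms <- function(distances) {
  d <- distances$distance_m
  if (any(d < 0)) {
    abort("Distances must be non-negative.", class = "elevrange_input_error")
  }
  if (sd(d) == 0) {
    abort("Distances are constant: unscalable.", class = "elevrange_input_error")
  }
  d2 <- d^2
  out <- tibble(
    point_id = distances$point_id,
    dist_congener = (d - mean(d)) / sd(d),
    dist_congener_sq = (d2 - mean(d2)) / sd(d2)
  )
  attr(out, "linked_pair") <- c("dist_congener", "dist_congener_sq")
  attr(out, "scaling") <- tibble(term = c("dist_congener", "dist_congener_sq"),
                                 center = c(mean(d), mean(d2)),
                                 scale = c(sd(d), sd(d2)))
  out
}

#' Compare the full (competition) model with the reduced model
#'
#' AICc comparison of a full N-mixture fit containing the quadratic
#' distance-to-congener pair against a reduced fit lacking it, both fitted
#' to the same data with the same detection structure. A positive
#' `delta_aicc = AICc(reduced) - AICc(full)` prefers the full model,
#' i.e. supports the competition hypothesis.
#'
#' @param full,reduced Converged [fit_nmixture()] objects on identical data.
#' @return An object of class `nmix_comparison`: a `table` of both models
#'   (k, logLik, AICc, Akaike weight), `delta_aicc`, and `preferred`.
#' @export
compare_competition_models <- function(full, reduced) {
  stopifnot(inherits(full, "nmix_fit"), inherits(reduced, "nmix_fit"))
  if (!identical(full$fingerprint, reduced$fingerprint)) {
    abort("Fits are not on the same data (fingerprints differ).",
          class = "elevrange_input_error")
  }
  det_f <- deparse(full$spec$detection)
  det_r <- deparse(reduced$spec$detection)
  if (!identical(det_f, det_r)) {
    abort("Fits use different detection structures.",
          class = "elevrange_input_error")
  }
  if (!full$converged || !reduced$converged) {
    warn("Comparing fits that did not both converge.",
         class = "elevrange_convergence")
  }
  aiccs <- c(full = full$aicc, reduced = reduced$aicc)
  delta <- unname(aiccs["reduced"] - aiccs["full"])
  w <- exp(-0.5 * (aiccs - min(aiccs)))
  w <- w / sum(w)
  structure(
    list(table = tibble(model = c("full", "reduced"),
                        k = c(full$n_params, reduced$n_params),
                        logLik = c(full$logLik, reduced$logLik),
                        AICc = unname(aiccs),
                        weight = unname(w)),
         delta_aicc = delta,
         preferred = if (delta > 0) "full" else "reduced"),
    class = "nmix_comparison"
  )
}

#' @export
print.nmix_comparison <- function(x, ...) {
  cat("<nmix_comparison>\n")
  print(as.data.frame(x$table), row.names = FALSE)
  cat(sprintf("  delta AICc (reduced - full) = %.3f; preferred: %s\n",
              x$delta_aicc, x$preferred))
  invisible(x)
}
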