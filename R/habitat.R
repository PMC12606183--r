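# Plot-level habitat covariates: tree-type proportions by cumulative
# diameter, the touch-pole understorey index, and the forest-floor
# principal-component index.

#' Tree-type proportions of cumulative diameter
#'
#' Per plot, the proportion of the cumulative stem diameter contributed by
#' each tree type (broadleaf, tree fern, palm); accounts for size
#' differences between trees. A plot with no stems yields a missing triple.
#'
#' @param stems Tibble with `point_id`, `type` (one of `"broadleaf"`,
#'   `"tree_fern"`, `"palm"`) and `diameter_cm` (> 0), or a `habitat_plots`
#'   object.
#' @param points Optional tibble (or character vector) of point ids so that
#'   stem-free plots appear as missing rows.
#' @return A tibble with `point_id`, `pct_broadleaf`, `pct_tree_fern`,
#'   `pct_palm`; the three proportions sum to 1 where any stems exist.
#' @export
#' @examples
#' st <- tibble::tibble(point_id = "P1",
#'                      type = c("broadleaf", "broadleaf", "tree_fern", "palm"),
#'                      diameter_cm = c(30, 20, 25, 25))
#' tree_proportions(st)  # 0.50, 0.25, 0.25
tree_proportions <- function(stems, points = NULL) {
  if (inherits(stems, "habitat_plots")) {
    points <- points %||% stems$points
    stems <- stems$stems
  }
  if (nrow(stems) > 0 && any(stems$diameter_cm <= 0)) {
    abort("Stem diameters must be positive.", class = "elevrange_input_error")
  }
  bad <- setdiff(unique(stems$type), c("broadleaf", "tree_fern", "palm"))
  if (length(bad) > 0) {
    abort(paste0("Unknown tree type(s): ", paste(bad, collapse = ", ")),
          class = "elevrange_input_error")
  }
  out <- stems |>
    group_by(.data$point_id) |>
    summarise(
      pct_broadleaf = sum(.data$diameter_cm[.data$type == "broadleaf"]) /
        sum(.data$diameter_cm),
      pct_tree_fern = sum(.data$diameter_cm[.data$type == "tree_fern"]) /
        sum(.data$diameter_cm),
      pct_palm = sum(.data$diameter_cm[.data$type == "palm"]) /
        sum(.data$diameter_cm),
      .groups = "drop"
    )
  if (!is.null(points)) {
    ids <- if (is.data.frame(points)) points$point_id else points
    out <- left_join(tibble(point_id = ids), out, by = "point_id")
  }
  out
}

#' Touch-pole understorey density index
#'
#' Arithmetic mean of the vegetation-touch counts over the 40 pole
#' placements of a plot (20 on each bisecting line); each count is the
#' number of 50 cm sections of a 3 m pole touched, so scores lie in 0..6.
#'
#' @param touches Tibble with `point_id`, `touches` (integers in 0..6;
#'   exactly 40 per plot), or a `habitat_plots` object.
#' @return A tibble with `point_id`, `understorey_index` in `[0, 6]`.
#' @export
understorey_index <- function(touches) {
  if (inherits(touches, "habitat_plots")) touches <- touches$touches
  if (any(touches$touches != round(touches$touches)) ||
      any(touches$touches < 0 | touches$touches > 6)) {
    abort("Touch counts must be integers in 0..6.", class = "elevrange_input_error")
  }
  counts <- dplyr::count(touches, .data$point_id)
  if (any(counts$n != 40)) {
    abort(paste0("Each plot needs exactly 40 touch-pole placements; offending: ",
                 paste(head(counts$point_id[counts$n != 40], 5), collapse = ", ")),
          class = "elevrange_input_error")
  }
  touches |>
    group_by(.data$point_id) |>
    summarise(understorey_index = mean(.data$touches), .groups = "drop")
}

#' Forest-floor principal-component index
#'
#' Averages litter depth and soil impact depth over each plot's five
#' quadrats, standardizes both plot-mean variables, and scores plots on the
#' first principal component of their 2 x 2 correlation matrix. The sign is
#' oriented so that larger litter depth gives a larger score (higher scores
#' represent thicker, deeper forest floors).
#'
#' @param quadrats Tibble with `point_id`, `litter_mm`, `soil_mm`, or a
#'   `habitat_plots` object.
#' @return A tibble with `point_id`, `forest_floor_pc1`; attributes
#'   `var_explained` (proportion of variance on PC1) and `loadings`.
#' @export
forest_floor_index <- function(quadrats) {
  if (inherits(quadrats, "habitat_plots")) quadrats <- quadrats$quadrats
  plot_means <- quadrats |>
    group_by(.data$point_id) |>
    summarise(litter = mean(.data$litter_mm), soil = mean(.data$soil_mm),
              .groups = "drop")
  if (nrow(plot_means) < 3) {
    abort("Need >= 3 plots with quadrat data.", class = "elevrange_design_error")
  }
  if (sd(plot_means$litter) == 0 || sd(plot_means$soil) == 0) {
    abort("Zero variance in litter or soil depth; PCA undefined.",
          class = "elevrange_design_error")
  }
  pc <- prcomp(plot_means[, c("litter", "soil")], center = TRUE, scale. = TRUE)
  scores <- pc$x[, 1]
  if (cor(scores, plot_means$litter) < 0) scores <- -scores
  out <- tibble(point_id = plot_means$point_id, forest_floor_pc1 = unname(scores))
  attr(out, "var_explained") <- pc$sdev[1]^2 / sum(pc$sdev^2)
  attr(out, "loadings") <- pc$rotation
  out
}

#' Assemble the model-ready site covariate table
#'
#' Joins habitat covariates with optional thermal-cost and
#' distance-to-congener covariates by `point_id`, log10-transforms the
#' understorey index (with an epsilon guard of half the smallest positive
#' value when zeros occur) so that it is approximately normal, and z-scores
#' every abundance covariate so magnitudes of change are comparable.
#' Scaling constants are stored for back-transformation.
#'
#' @param habitat Tibble keyed by `point_id` with habitat covariate columns
#'   (e.g. from [tree_proportions()], [understorey_index()],
#'   [forest_floor_index()] joined together).
#' @param thermal Optional tibble `point_id`, `thermal_cost`.
#' @param distances Optional tibble `point_id`, `distance_m`; expanded into
#'   the linked quadratic pair via [competition_terms()].
#' @return A tibble with `point_id` and z-scored covariates; attribute
#'   `scaling` records per-column centre/scale (and the log10 epsilon).
#' @export
assemble_covariates <- function(habitat, thermal = NULL, distances = NULL) {
  out <- as_tibble(habitat)
  if (!"point_id" %in% names(out)) {
    abort("`habitat` must have a `point_id` column.", class = "elevrange_input_error")
  }
  join_checked <- function(x, y, what) {
    missing <- setdiff(x$point_id, y$point_id)
    if (length(missing) > 0) {
      abort(paste0(what, " missing for point(s): ",
                   paste(head(missing, 5), collapse = ", ")),
            class = "elevrange_input_error")
    }
    left_join(x, y, by = "point_id")
  }
  if (!is.null(thermal)) out <- join_checked(out, thermal, "Thermal costs")
  if (!is.null(distances)) {
    dz <- competition_terms(distances)
    out <- join_checked(out, dz, "Distances")
  }

  eps_used <- NA_real_
  if ("understorey_index" %in% names(out)) {
    u <- out$understorey_index
    if (any(u == 0, na.rm = TRUE)) {
      pos <- u[u > 0 & !is.na(u)]
      if (length(pos) == 0) {
        abort("Understorey index is zero everywhere; cannot log-transform.",
              class = "elevrange_input_error")
      }
      eps_used <- min(pos) / 2
      u <- u + eps_used
    }
    out$understorey_index <- log10(u)
  }

  num_cols <- setdiff(names(out)[vapply(out, is.numeric, logical(1))],
                      c("dist_congener", "dist_congener_sq"))  # already scaled
  scaling <- purrr::map(num_cols, function(cl) {
    v <- out[[cl]]
    s <- sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) {
      abort(sprintf("Covariate '%s' is constant (sd 0): unscalable.", cl),
            class = "elevrange_input_error")
    }
    m <- mean(v, na.rm = TRUE)
    out[[cl]] <<- (v - m) / s
    tibble(term = cl, center = m, scale = s)
  }) |> purrr::list_rbind()
  attr(out, "scaling") <- scaling
  attr(out, "log10_eps") <- eps_used
  out
}
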