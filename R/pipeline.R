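# End-to-end orchestration: synthetic (or user-supplied) inputs -> lapse
# models -> thermoregulation fits -> cost profiles and ceilings -> habitat
# covariates -> distances -> two-step N-mixture fits -> bootstrap GOF ->
# tables, figures and a machine-readable manifest.

#' Pipeline configuration
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master integer seed; every stage derives its own sub-seed
#'   deterministically from it.
#' @param truth An [elev_truth()] block for synthetic runs.
#' @param inputs Optional named list of CSV paths (`loggers`,
#'   `respirometry`, `counts_long`, `habitat`, `territories`, `points`) to
#'   run on user data instead of simulating; files must exist.
#' @param species Species to analyse; default all species in `truth$thermo`.
#' @param subordinate,dominant The competition pair: the subordinate species
#'   receives the distance-to-dominant quadratic term and the full/reduced
#'   comparison.
#' @param reciprocal Also fit the reciprocal competition model (distance to
#'   the subordinate, for the dominant species); reported separately.
#' @param n_points,n_loggers,days,visits_per_point,elevation_range,n_birds,
#'   ridges,territories_per_ridge Synthetic study dimensions.
#' @param day_window Clock-time day window (night is its complement).
#' @param threshold Sustainability threshold in multiples of BMR (> 1).
#' @param K Truncation policy for N-mixture fits (`"auto"` or a count).
#' @param n_boot Bootstrap replicates for goodness of fit.
#' @param make_figures Write cost-profile figures (PNG) when a graphics
#'   device is available.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            truth = elev_truth(seed = seed),
                            inputs = NULL,
                            species = names(truth$thermo),
                            subordinate = "C_frantzii",
                            dominant = "C_mexicanus",
                            reciprocal = FALSE,
                            n_points = 83, n_loggers = 31, days = 45,
                            visits_per_point = c(1, 7),
                            elevation_range = c(1200, 2200),
                            n_birds = c(C_mexicanus = 28, C_frantzii = 11,
                                        H_leucophrys = 8, A_brunneinucha = 14),
                            ridges = 5, territories_per_ridge = 6,
                            day_window = c("05:30", "18:30"),
                            threshold = 2, K = "auto", n_boot = 199,
                            make_figures = TRUE) {
  if (threshold <= 1) {
    abort("`threshold` must exceed 1.", class = "elevrange_input_error")
  }
  if (!is.null(inputs)) {
    missing_files <- inputs[!vapply(unlist(inputs), file.exists, logical(1))]
    if (length(missing_files) > 0) {
      abort(paste0("Input file(s) not found: ",
                   paste(unlist(missing_files), collapse = ", ")),
            class = "elevrange_input_error")
    }
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), truth = truth,
         inputs = inputs, species = species,
         subordinate = subordinate, dominant = dominant,
         reciprocal = isTRUE(reciprocal),
         n_points = n_points, n_loggers = n_loggers, days = days,
         visits_per_point = visits_per_point,
         elevation_range = elevation_range, n_birds = n_birds,
         ridges = ridges, territories_per_ridge = territories_per_ridge,
         day_window = day_window, threshold = threshold, K = K,
         n_boot = n_boot, make_figures = isTRUE(make_figures)),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads scalar fields of [pipeline_config()] plus an optional nested
#' `truth:` block whose entries override [elev_truth()] defaults.
#'
#' @param path YAML file path.
#' @param out_dir Overrides the file's `out_dir` when given.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  raw <- yaml::read_yaml(path)
  truth_args <- raw$truth %||% list()
  raw$truth <- NULL
  if (!is.null(out_dir)) raw$out_dir <- out_dir
  if (is.null(raw$out_dir)) {
    abort("Config must set `out_dir`.", class = "elevrange_input_error")
  }
  seed <- raw$seed %||% 1L
  truth <- do.call(elev_truth, c(truth_args, list(seed = as.integer(seed))))
  do.call(pipeline_config, c(raw, list(truth = truth)))
}

# Simulate the five input tables of the field study.
simulate_field_study <- function(cfg) {
  tr <- cfg$truth
  s <- cfg$seed
  points <- simulate_points(cfg$n_points, cfg$elevation_range,
                            seed = derive_seed(s, 1))
  loggers <- generate_loggers(tr, cfg$n_loggers, cfg$elevation_range,
                              days = cfg$days, seed = derive_seed(s, 2))
  resp <- purrr::imap(tr$thermo, function(tm, sp) {
    nb <- cfg$n_birds[[sp]] %||% 12
    generate_respirometry(tm, n_birds = nb, treatments_per_bird = c(1, 4),
                          noise_sd = 0.05 * tm$bmr, species = sp,
                          seed = derive_seed(s, 3 + match(sp, names(tr$thermo))))
  }) |> purrr::list_rbind()
  habitat <- generate_habitat(tr, points, seed = derive_seed(s, 8))
  territories <- generate_territories(tr, cfg$ridges, cfg$territories_per_ridge,
                                      species = c(cfg$dominant, cfg$subordinate),
                                      seed = derive_seed(s, 9))
  list(points = points, loggers = loggers, respirometry = resp,
       habitat = habitat, territories = territories)
}

# Write the input tables as documented CSVs.
write_input_tables <- function(sim, dir) {
  readr::write_csv(sim$loggers, file.path(dir, "loggers.csv"))
  readr::write_csv(sim$respirometry, file.path(dir, "respirometry.csv"))
  readr::write_csv(sim$points, file.path(dir, "points.csv"))
  hb <- bind_rows(
    sim$habitat$stems |> mutate(component = "stem", .before = 1),
    sim$habitat$touches |> mutate(component = "touch", .before = 1),
    sim$habitat$quadrats |> mutate(component = "quadrat", .before = 1)
  )
  readr::write_csv(hb, file.path(dir, "habitat.csv"))
  readr::write_csv(as_tibble(sim$territories), file.path(dir, "territories.csv"))
  invisible(NULL)
}

# Read user-supplied input tables (the same formats write_input_tables
# produces).
read_input_tables <- function(inputs) {
  hb_long <- readr::read_csv(inputs$habitat, show_col_types = FALSE)
  habitat <- structure(
    list(stems = hb_long |> filter(.data$component == "stem") |>
           select("point_id", "type", "diameter_cm"),
         touches = hb_long |> filter(.data$component == "touch") |>
           select("point_id", "placement", "touches"),
         quadrats = hb_long |> filter(.data$component == "quadrat") |>
           select("point_id", "quadrat", "litter_mm", "soil_mm")),
    class = "habitat_plots"
  )
  list(
    points = readr::read_csv(inputs$points, show_col_types = FALSE),
    loggers = readr::read_csv(inputs$loggers, show_col_types = FALSE),
    respirometry = readr::read_csv(inputs$respirometry, show_col_types = FALSE),
    habitat = habitat,
    territories = readr::read_csv(inputs$territories, show_col_types = FALSE),
    counts_long = readr::read_csv(inputs$counts_long, show_col_types = FALSE)
  )
}

#' Run the full elevational-range analysis pipeline
#'
#' Executes, in order: input simulation (or loading), day/night thermal
#' summaries and lapse models, thermoregulation fits, nightly cost profiles
#' and thermal ceilings, habitat covariates, distance-to-congener terms,
#' two-step N-mixture fitting per species (detection selection, then
#' abundance models with habitat plus thermal cost, plus the full/reduced
#' competition comparison for the subordinate congener), and parametric-
#' bootstrap goodness of fit on the subordinate's saturated model. All
#' tables, a JSON results manifest and a JSON-lines log are written to
#' `config$out_dir`. Synthetic runs with the same config and seed produce a
#' byte-identical manifest.
#'
#' @param config A [pipeline_config()] (or path to a YAML config).
#' @param stages Character vector of stages to write outputs for; one of
#'   `"all"` (default) or a subset of `simulate`, `thermal`, `metabolic`,
#'   `niche`, `habitat`, `fit`, `gof`, `report`. Earlier stages are always
#'   computed in memory as needed.
#' @return Invisibly, the results bundle (a named list).
#' @export
run_pipeline <- function(config, stages = "all") {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "thermal", "metabolic", "niche", "habitat",
                  "fit", "gof", "report")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) {
    abort(paste0("Unknown stage(s): ", paste(bad, collapse = ", ")),
          class = "elevrange_input_error")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "log.jsonl")
  unlink(log_path)
  log_line <- function(...) {
    entry <- list(...)
    cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
        file = log_path, sep = "", append = TRUE)
  }
  run_stage <- function(stage, expr) {
    tryCatch({
      res <- force(expr)
      log_line(stage = stage, status = "done")
      res
    }, error = function(e) {
      log_line(stage = stage, status = "failed", error = conditionMessage(e))
      abort(sprintf("Pipeline halted at stage '%s': %s", stage,
                    conditionMessage(e)),
            class = "elevrange_pipeline_error", parent = e)
    })
  }
  log_line(event = "start", package = "elevrange",
           version = as.character(utils::packageVersion("elevrange")),
           seed = config$seed)
  tr <- config$truth
  out <- list(config = config)

  # ---- inputs -------------------------------------------------------------
  synthetic <- is.null(config$inputs)
  sim <- run_stage("simulate", {
    if (synthetic) simulate_field_study(config) else read_input_tables(config$inputs)
  })
  out$inputs <- sim

  # ---- thermal environment ------------------------------------------------
  thermal <- run_stage("thermal", {
    summaries <- suppressWarnings(summarize_days(sim$loggers, config$day_window))
    lapse <- purrr::map(
      setNames(nm = c("night_mean", "day_mean", "day_max", "day_min")),
      function(r) fit_lapse_model(summaries, r)
    )
    list(summaries = summaries, lapse = lapse)
  })
  out$thermal <- thermal

  # ---- metabolic models ---------------------------------------------------
  thermo_fits <- run_stage("metabolic", {
    purrr::map(setNames(nm = config$species), function(sp) {
      fit_thermoregulation(sim$respirometry, species = sp)
    })
  })
  out$thermo <- thermo_fits

  # ---- physiological niche ------------------------------------------------
  niche <- run_stage("niche", {
    purrr::map(setNames(nm = config$species), function(sp) {
      costs <- suppressWarnings(
        nightly_cost_by_logger(thermo_fits[[sp]], sim$loggers, config$day_window)
      )
      profile <- fit_cost_elevation(costs, threshold = config$threshold,
                                    species = sp)
      list(costs = costs, profile = profile, ceiling = thermal_ceiling(profile))
    })
  })
  out$niche <- niche

  # ---- habitat covariates and distances -----------------------------------
  covariates <- run_stage("habitat", {
    hab <- tree_proportions(sim$habitat, points = sim$points) |>
      inner_join(understorey_index(sim$habitat), by = "point_id") |>
      inner_join(forest_floor_index(sim$habitat), by = "point_id")
    distances <- distance_to_congener(sim$points, sim$territories,
                                      species = config$dominant)
    distances_recip <- distance_to_congener(sim$points, sim$territories,
                                            species = config$subordinate)
    # analysis-side thermal cost: the estimated profile evaluated at each
    # point's elevation (one column per non-flat species)
    est_cost <- purrr::map(setNames(nm = config$species), function(sp) {
      predict_cost(niche[[sp]]$profile, sim$points$elevation)$cost
    })
    list(habitat = hab, distances = distances, distances_recip = distances_recip,
         est_cost = est_cost)
  })
  out$covariates <- covariates

  # ---- surveys (synthetic only): generated from measured covariates and
  # the TRUE thermal cost curve, so generation never depends on fitting ----
  counts <- run_stage("survey", {
    if (synthetic) {
      # generation-side covariates: measured habitat, TRUE thermal cost at
      # the season-mean night temperature, distances; all z-scored
      night_shape <- mean_night_diel(config$day_window)
      purrr::map(setNames(nm = config$species), function(sp) {
        tm <- tr$thermo[[sp]]
        gt <- covariates$habitat
        e <- sim$points$elevation[match(gt$point_id, sim$points$point_id)]
        tnight <- tr$lapse_intercept + tr$lapse_slope * e +
          tr$diel_amplitude * night_shape
        gt$thermal_cost <- cost_multiple(tm, tnight)
        if (sd(gt$thermal_cost) == 0) gt$thermal_cost <- NULL
        assembled <- assemble_covariates(gt, distances = covariates$distances)
        generate_survey(tr, sim$points, config$visits_per_point,
                        assembled, species = sp,
                        seed = derive_seed(config$seed, 20 + match(sp, config$species)))
      })
    } else {
      cl <- sim$counts_long
      purrr::map(setNames(nm = config$species), function(sp) {
        count_data(filter(cl, .data$species == sp),
                   site_covariates = analysis_site_table(config, sp, covariates,
                                                         thermo_fits, sim))
      })
    }
  })
  out$counts <- counts

  # ---- abundance fits -----------------------------------------------------
  fits <- run_stage("fit", {
    purrr::map(setNames(nm = config$species), function(sp) {
      site_tab <- analysis_site_table(config, sp, covariates, thermo_fits, sim)
      cd <- count_data(counts[[sp]]$counts_long, site_tab)
      sel <- select_detection_model(cd, zip = TRUE, K = config$K)
      ab_terms <- attr(site_tab, "abundance_terms")
      full_spec <- nmix_spec(
        abundance = if (length(ab_terms) == 0) ~1 else stats::reformulate(ab_terms),
        detection = sel$best_detection, zip = TRUE, K = config$K
      )
      full <- fit_nmixture(cd, full_spec)
      comparison <- NULL
      if (identical(sp, config$subordinate)) {
        red_terms <- setdiff(ab_terms, c("dist_congener", "dist_congener_sq"))
        red_spec <- nmix_spec(
          abundance = if (length(red_terms) == 0) ~1 else stats::reformulate(red_terms),
          detection = sel$best_detection, zip = TRUE, K = config$K
        )
        reduced <- fit_nmixture(cd, red_spec)
        comparison <- compare_competition_models(full, reduced)
      }
      list(data = cd, selection = sel, fit = full, comparison = comparison)
    })
  })
  out$fits <- fits

  # ---- goodness of fit ----------------------------------------------------
  gof <- run_stage("gof", {
    sp <- config$subordinate
    if (sp %in% config$species && fits[[sp]]$fit$converged) {
      bootstrap_gof(fits[[sp]]$fit, n_boot = config$n_boot,
                    seed = derive_seed(config$seed, 40))
    } else NULL
  })
  out$gof <- gof

  # ---- outputs ------------------------------------------------------------
  run_stage("report", {
    write_pipeline_outputs(out, stages)
  })
  log_line(event = "end")
  invisible(out)
}

# Season-mean of the diel shape over the night window (closed form over the
# 30-min reading grid).
mean_night_diel <- function(day_window = c("05:30", "18:30")) {
  w <- parse_clock(day_window)
  hrs <- seq(0, 23.5, by = 0.5)
  night <- hrs < w[1] | hrs >= w[2]
  mean(diel_shape(hrs[night]))
}

# Site covariate table for one species' abundance model, with the terms the
# hypotheses request: habitat always; thermal cost unless the species'
# thermoregulation is flat; the quadratic distance pair for the subordinate
# (and, if requested, the reciprocal distance for the dominant).
analysis_site_table <- function(config, sp, covariates, thermo_fits, sim) {
  hab <- covariates$habitat
  ab_terms <- c("pct_tree_fern", "pct_palm", "understorey_index",
                "forest_floor_pc1")
  thermal <- NULL
  if (thermo_fits[[sp]]$variant != "flat") {
    thermal <- tibble(point_id = hab$point_id,
                      thermal_cost = covariates$est_cost[[sp]])
    if (sd(thermal$thermal_cost) > 0) {
      ab_terms <- c(ab_terms, "thermal_cost")
    } else {
      thermal <- NULL
    }
  }
  distances <- NULL
  if (identical(sp, config$subordinate)) {
    distances <- covariates$distances
    ab_terms <- c(ab_terms, "dist_congener", "dist_congener_sq")
  } else if (config$reciprocal && identical(sp, config$dominant)) {
    distances <- covariates$distances_recip
    ab_terms <- c(ab_terms, "dist_congener", "dist_congener_sq")
  }
  tab <- assemble_covariates(hab, thermal = thermal, distances = distances)
  attr(tab, "abundance_terms") <- ab_terms
  tab
}

# Write every stage's tables, figures and the manifest. File names are
# relative inside the manifest so reruns are byte-identical.
write_pipeline_outputs <- function(out, stages) {
  cfg <- out$config
  dir <- cfg$out_dir
  files <- character(0)
  emit <- function(df, name) {
    readr::write_csv(df, file.path(dir, name))
    files <<- c(files, name)
  }

  if ("simulate" %in% stages && is.null(cfg$inputs)) {
    write_input_tables(out$inputs, dir)
    counts_long <- purrr::imap(out$counts, function(cd, sp) {
      mutate(cd$counts_long, species = sp, .before = 1)
    }) |> purrr::list_rbind()
    emit(counts_long, "counts_long.csv")
    files <- c(files, "loggers.csv", "respirometry.csv", "points.csv",
               "habitat.csv", "territories.csv")
  }
  if ("thermal" %in% stages) {
    emit(purrr::map(out$thermal$lapse, glance) |> purrr::list_rbind(),
         "lapse_models.csv")
  }
  if ("metabolic" %in% stages) {
    emit(purrr::map(out$thermo, glance) |> purrr::list_rbind(),
         "thermo_models.csv")
  }
  if ("niche" %in% stages) {
    emit(purrr::imap(out$niche, function(x, sp) {
      mutate(x$costs, species = sp, .before = 1)
    }) |> purrr::list_rbind(), "cost_profiles.csv")
    emit(purrr::map(out$niche, function(x) glance(x$profile)) |>
           purrr::list_rbind(), "ceilings.csv")
    if (cfg$make_figures && capabilities("png")) {
      for (sp in names(out$niche)) {
        f <- file.path(dir, sprintf("cost_profile_%s.png", sp))
        tryCatch({
          grDevices::png(f, width = 1200, height = 900, res = 150)
          print(autoplot(out$niche[[sp]]$profile))
          grDevices::dev.off()
        }, error = function(e) try(grDevices::dev.off(), silent = TRUE))
      }
    }
  }
  if ("habitat" %in% stages) {
    hab_all <- out$covariates$habitat
    emit(hab_all, "covariates.csv")
    emit(out$covariates$distances, "distances.csv")
  }
  if ("fit" %in% stages) {
    emit(purrr::imap(out$fits, function(x, sp) {
      mutate(x$selection$ranking, species = sp, .before = 1)
    }) |> purrr::list_rbind(), "detection_ranking.csv")
    emit(purrr::imap(out$fits, function(x, sp) {
      mutate(tidy(x$fit), species = sp, .before = 1)
    }) |> purrr::list_rbind(), "abundance_fits.csv")
    comparisons <- purrr::imap(out$fits, function(x, sp) {
      if (is.null(x$comparison)) return(NULL)
      mutate(x$comparison$table, species = sp, .before = 1)
    }) |> purrr::list_rbind()
    if (nrow(comparisons) > 0) emit(comparisons, "competition_comparison.csv")
    fits_json <- purrr::imap(out$fits, function(x, sp) {
      list(species = sp,
           detection = x$selection$best_label,
           coefficients = as.data.frame(tidy(x$fit)),
           logLik = x$fit$logLik, AICc = x$fit$aicc,
           psi = x$fit$psi, K = x$fit$K, converged = x$fit$converged)
    })
    jsonlite::write_json(fits_json, file.path(dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, "fits.json")
  }
  if ("gof" %in% stages && !is.null(out$gof)) {
    emit(glance(out$gof), "gof.csv")
  }
  if ("report" %in% stages) {
    manifest <- list(
      package = "elevrange",
      version = as.character(utils::packageVersion("elevrange")),
      seed = cfg$seed,
      species = cfg$species,
      threshold = cfg$threshold,
      n_points = cfg$n_points, n_loggers = cfg$n_loggers, days = cfg$days,
      n_boot = cfg$n_boot,
      files = sort(unique(files)),
      results = list(
        lapse = purrr::map(out$thermal$lapse, function(l) {
          list(intercept = l$intercept, slope = l$slope, r = l$r)
        }),
        thermo = purrr::map(out$thermo, function(m) {
          list(variant = m$variant, bmr = m$bmr,
               t_lc = m$t_lc %||% NULL, c_min = m$c_min %||% NULL)
        }),
        ceilings = purrr::map(out$niche, function(x) {
          list(ceiling_m = x$ceiling$ceiling_m, reason = x$ceiling$reason)
        }),
        detection = purrr::map(out$fits, function(x) x$selection$best_label),
        aicc = purrr::map(out$fits, function(x) x$fit$aicc),
        competition = if (!is.null(out$fits[[cfg$subordinate]]$comparison)) {
          cmp <- out$fits[[cfg$subordinate]]$comparison
          list(delta_aicc = cmp$delta_aicc, preferred = cmp$preferred)
        } else NULL,
        gof = if (!is.null(out$gof)) {
          list(p_chisq = out$gof$p_chisq, p_ss = out$gof$p_ss,
               c_hat = out$gof$c_hat)
        } else NULL
      )
    )
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(files)
}
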