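# Habitat covariates: tree proportions, understorey index, forest-floor PCA,
# and covariate assembly.

test_that("tree proportions partition cumulative diameter", {
  st <- tibble::tibble(point_id = "P1",
                       type = c("broadleaf", "broadleaf", "tree_fern", "palm"),
                       diameter_cm = c(30, 20, 25, 25))
  tp <- tree_proportions(st)
  expect_equal(unlist(tp[1, -1], use.names = FALSE), c(0.50, 0.25, 0.25))
  only_palm <- tibble::tibble(point_id = "P2", type = "palm", diameter_cm = 12)
  expect_equal(unlist(tree_proportions(only_palm)[1, -1], use.names = FALSE),
               c(0, 0, 1))
  # stem-free plot encoded as a missing triple
  tp3 <- tree_proportions(st, points = c("P1", "P9"))
  expect_true(all(is.na(tp3[tp3$point_id == "P9", -1])))
  expect_error(tree_proportions(dplyr::mutate(st, diameter_cm = -1)), "positive")
})

test_that("tree proportions sum to 1 for any non-empty plot (property)", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    st <- tibble::tibble(point_id = "P1",
                         type = sample(c("broadleaf", "tree_fern", "palm"), n,
                                       replace = TRUE),
                         diameter_cm = runif(n, 1, 60))
    tp <- tree_proportions(st)
    expect_equal(sum(tp[1, -1]), 1, tolerance = 1e-9)
  }
})

test_that("understorey index is the mean touch score with hard bounds", {
  mk <- function(v) tibble::tibble(point_id = "P1", placement = 1:40, touches = v)
  expect_equal(understorey_index(mk(rep(6, 40)))$understorey_index, 6)
  expect_equal(understorey_index(mk(rep(0, 40)))$understorey_index, 0)
  expect_equal(understorey_index(mk(rep(c(2, 4), each = 20)))$understorey_index, 3)
  expect_error(understorey_index(mk(rep(7, 40))), "0..6")
  expect_error(understorey_index(tibble::tibble(point_id = "P1",
                                                placement = 1:39,
                                                touches = rep(1, 39))),
               "exactly 40")
  # bounds hold on generated data
  hb <- generate_habitat(elev_truth(), simulate_points(30, seed = 3), seed = 4)
  ui <- understorey_index(hb)
  expect_true(all(ui$understorey_index >= 0 & ui$understorey_index <= 6))
})

test_that("forest-floor PCA has the closed-form behaviour for r = 1 and r = 0", {
  # perfectly correlated: score = sqrt(2) * z, PC1 explains 100%
  z <- c(-1.2, -0.3, 0.4, 1.5, 2.1)
  q1 <- tibble::tibble(point_id = rep(sprintf("P%d", 1:5), each = 5),
                       quadrat = rep(1:5, 5),
                       litter_mm = rep(30 + 5 * z, each = 5),
                       soil_mm = rep(20 + 3 * z, each = 5))
  ff <- forest_floor_index(q1)
  zz <- (z - mean(z)) / sd(z)
  expect_equal(ff$forest_floor_pc1, sqrt(2) * zz, tolerance = 1e-9)
  expect_equal(attr(ff, "var_explained"), 1, tolerance = 1e-12)
  # exactly uncorrelated sample: PC1 explains exactly 50%
  a <- c(-1, 1, -1, 1); b <- c(-1, -1, 1, 1)  # orthogonal, mean 0
  q0 <- tibble::tibble(point_id = rep(sprintf("P%d", 1:4), each = 5),
                       quadrat = rep(1:5, 4),
                       litter_mm = rep(30 + a, each = 5),
                       soil_mm = rep(20 + b, each = 5))
  expect_equal(attr(forest_floor_index(q0), "var_explained"), 0.5,
               tolerance = 1e-12)
})

test_that("forest-floor index is sign-oriented and unit invariant", {
  hb <- generate_habitat(elev_truth(), simulate_points(40, seed = 5), seed = 6)
  ff <- forest_floor_index(hb)
  pm <- dplyr::summarise(dplyr::group_by(hb$quadrats, point_id),
                         litter = mean(litter_mm))
  expect_gt(cor(ff$forest_floor_pc1, pm$litter), 0)
  # mm -> cm rescale leaves scores unchanged
  q_cm <- dplyr::mutate(hb$quadrats, litter_mm = litter_mm / 10,
                        soil_mm = soil_mm / 10)
  expect_equal(forest_floor_index(q_cm)$forest_floor_pc1,
               ff$forest_floor_pc1, tolerance = 1e-9)
  # flipping the raw sign of both variables flips no scores after orientation
  q_neg <- dplyr::mutate(hb$quadrats, litter_mm = -litter_mm, soil_mm = -soil_mm)
  expect_equal(forest_floor_index(q_neg)$forest_floor_pc1,
               -ff$forest_floor_pc1, tolerance = 1e-9)
  expect_error(forest_floor_index(dplyr::mutate(hb$quadrats, litter_mm = 1)),
               "variance")
})

test_that("assembled covariates are z-scored with stored scaling", {
  hab <- tibble::tibble(point_id = sprintf("P%d", 1:6),
                        pct_tree_fern = c(0, 0.1, 0.2, 0.5, 0.8, 0.9),
                        understorey_index = c(1, 10, 100, 1, 10, 100))
  out <- assemble_covariates(hab)
  for (cl in c("pct_tree_fern", "understorey_index")) {
    expect_equal(mean(out[[cl]]), 0, tolerance = 1e-9)
    expect_equal(sd(out[[cl]]), 1, tolerance = 1e-9)
  }
  # log10 {1,10,100,...} -> {0,1,2,...} -> z-scores with the sample sd
  v <- rep(c(0, 1, 2), 2)
  expect_equal(out$understorey_index, (v - mean(v)) / sd(v), tolerance = 1e-9)
  expect_true(is.data.frame(attr(out, "scaling")))
  # constant covariate is unscalable
  expect_error(assemble_covariates(dplyr::mutate(hab, pct_tree_fern = 0.5)),
               "unscalable")
  # missing join keys are named
  thermal <- tibble::tibble(point_id = sprintf("P%d", 1:5), thermal_cost = 1:5)
  expect_error(assemble_covariates(hab, thermal = thermal), "P6")
})

test_that("understorey zeros are guarded before the log transform", {
  hab <- tibble::tibble(point_id = sprintf("P%d", 1:4),
                        understorey_index = c(0, 2, 4, 6))
  out <- assemble_covariates(hab)
  expect_true(all(is.finite(out$understorey_index)))
  expect_equal(attr(out, "log10_eps"), 1)  # half the smallest positive value
})
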