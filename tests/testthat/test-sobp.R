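test_that("the combined peak dose is the weighted layer sum", {
  lib <- make_fixtures("toy-library-2")
  one <- combined_peak_dose(c(1, 0), lib)
  expect_equal(one$dose, lib$peak[, 1])
  both <- combined_peak_dose(c(0.5, 2), lib)
  expect_equal(both$dose, 0.5 * lib$peak[, 1] + 2 * lib$peak[, 2])
  expect_equal(combined_peak_dose(c(1, 2), lib)$dose * 2,
               combined_peak_dose(c(2, 4), lib)$dose)
  expect_error(combined_peak_dose(1, lib), class = "minibeamr_config_error")
})

test_that("the flatness fitness is the window max-minus-min", {
  z <- seq(0, 100, by = 0.5)
  flat <- dose_library(z, 1, matrix(3, length(z)))
  expect_equal(sobp_fitness(1, flat, c(10, 90)), 0)
  ramp <- dose_library(z, 1, matrix(0.25 * z, length(z)))
  expect_equal(sobp_fitness(1, ramp, c(10, 90)), 0.25 * 80)
  expect_equal(sobp_fitness(1, ramp, c(10, 90), type = "relative"),
               0.25 * 80 / mean(0.25 * z[z >= 10 & z <= 90]) * 100)
  # translation invariance of the absolute form
  shifted <- dose_library(z, 1, matrix(0.25 * z + 7, length(z)))
  expect_equal(sobp_fitness(1, shifted, c(10, 90)),
               sobp_fitness(1, ramp, c(10, 90)))
  expect_error(sobp_fitness(1, ramp, c(200, 300)),
               class = "minibeamr_config_error")
})

test_that("GA configuration validates its hyperparameters", {
  expect_error(ga_config(), class = "minibeamr_config_error") # seed mandatory
  expect_error(ga_config(population_size = 1, seed = 1),
               class = "minibeamr_config_error")
  expect_error(ga_config(crossover_rate = 1.2, seed = 1),
               class = "minibeamr_config_error")
})

test_that("the GA is deterministic under a fixed seed and converges monotonically", {
  lib <- make_fixtures("toy-library-5")
  ctrl <- ga_config(population_size = 30, generations = 60, seed = 11)
  p1 <- ga_optimize(lib, attr(lib, "flat_window"), ctrl)
  p2 <- ga_optimize(lib, attr(lib, "flat_window"), ctrl)
  expect_identical(p1$weights, p2$weights)
  expect_true(all(diff(p1$history$best_fitness) <= 0))
})

test_that("the GA recovers planted weights on an exactly flattenable library", {
  lib <- make_fixtures("toy-library-5")
  plan <- ga_optimize(lib, attr(lib, "flat_window"), ga_config(seed = 3))
  w_star <- attr(lib, "planted_weights")
  expect_lt(max(abs(plan$weights / plan$weights[5] - w_star) / w_star), 0.02)
  expect_lt(plan$max_dose_error_pct, 0.5)
})

test_that("a two-layer optimum matches an exhaustive grid search", {
  lib <- make_fixtures("toy-library-2")
  window <- c(160, 172)
  ratios <- seq(0.2, 3, by = 0.001)
  f <- vapply(ratios, function(r) sobp_fitness(c(r, 1), lib, window),
              numeric(1))
  oracle <- ratios[which.min(f)]
  plan <- ga_optimize(lib, window, ga_config(seed = 5))
  expect_equal(plan$weights[1], oracle, tolerance = 0.01)
})

test_that("plan accessors expose tidy weights and a one-row summary", {
  lib <- make_fixtures("toy-library-5")
  plan <- ga_optimize(lib, attr(lib, "flat_window"),
                      ga_config(population_size = 20, generations = 40,
                                seed = 2))
  td <- tidy(plan)
  expect_named(td, c("energy_MeV", "weight"))
  expect_equal(nrow(td), 5)
  expect_equal(td$weight[5], 1)
  gl <- glance(plan)
  expect_equal(gl$n_layers, 5)
  expect_equal(gl$seed, 2L)
})

test_that("converged minibeam patterns demand heavier proximal layers", {
  # engine-derived libraries: the converging geometry lowers the relative
  # contribution of the deep layers at the proximal window, so normalized
  # low-energy weights come out higher than in the straight reference
  energies <- c(150, 154, 158, 162, 166)
  s1 <- make_scenario("config1")
  s3p <- make_scenario("config3p")
  ft <- build_field_table(s3p, energies, rm_tab)
  lib1 <- sobp_dose_library(energies, source = "engine", scenario = s1,
                            model = rm_tab, peak_align = c(157, 187))
  lib3 <- sobp_dose_library(energies, source = "engine", scenario = s3p,
                            field_table = ft, model = rm_tab,
                            peak_align = c(157, 187))
  w1 <- ga_optimize(lib1, c(157, 187), ga_config(seed = 9))$weights
  w3 <- ga_optimize(lib3, c(157, 187), ga_config(seed = 9))$weights
  expect_gt(sum(w3[1:2]), sum(w1[1:2]))
})
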