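test_that("slit positions and tilts follow the divergent-collimator layout", {
  sl <- slit_positions(pmbrt_collimator())
  expect_equal(sl$x1_mm, seq(-28, 28, by = 4))
  expect_equal(sl$tilt_rad[sl$x1_mm == 0], 0)
  # antisymmetry under x -> -x
  expect_equal(sl$x1_mm, -rev(sl$x1_mm))
  expect_equal(sl$tilt_rad, -rev(sl$tilt_rad))
  # tilt magnitude: 0.025 deg/mm pointing away from the axis
  expect_equal(sl$tilt_rad[sl$x1_mm == 28], 0.7 * pi / 180)
  sl6 <- slit_positions(pmbrt_collimator(ctc = 6))
  expect_equal(range(sl6$x1_mm), c(-42, 42))
})

test_that("collimator construction validates its geometry", {
  expect_error(pmbrt_collimator(n_slits = 14), class = "minibeamr_config_error")
  expect_error(pmbrt_collimator(slit_width = 5, ctc = 4),
               class = "minibeamr_config_error")
  expect_error(pmbrt_collimator(thickness = 0), class = "minibeamr_config_error")
})

test_that("scenario presets encode the five configurations", {
  s1 <- make_scenario("config1")
  expect_equal(s1$collimator$ctc, 4)
  expect_equal(s1$field_region, "none")
  expect_equal(s1$air_gap, 70)
  expect_equal(s1$phantom_size, c(100, 100, 300))
  expect_equal(s1$dose_voxels, c(0.1, 2, 1))
  expect_equal(s1$spot_grid$n_x, 31)
  expect_equal(s1$spot_grid$dy, 3)

  s2 <- make_scenario("config2")
  expect_equal(s2$collimator$ctc, 6)
  expect_equal(s2$field_region, "dipole")
  expect_equal(s2$dipole_thickness, 50)
  expect_equal(s2$collimator$mode, "static-multislit")

  s3p <- make_scenario("config3p")
  expect_equal(s3p$field_region, "phantom")
  expect_equal(s3p$collimator$mode, "dynamic-aperture")

  expect_error(make_scenario("config9"), "config1",
               class = "minibeamr_config_error")
})

test_that("dynamic aperture feeds exactly the aligned slit", {
  coll <- pmbrt_collimator(ctc = 6, mode = "dynamic-aperture")
  w <- slit_transmission_weights(12, 3, coll)
  expect_equal(sum(w$weight != 0), 1)
  expect_equal(w$weight[w$x1_mm == 12], 1)
  # a spot between slits opens nothing
  w_off <- slit_transmission_weights(3, 3, coll)
  expect_equal(sum(w_off$weight), 0)
})

test_that("static transmission reproduces the Gaussian aperture integrals", {
  coll <- pmbrt_collimator(ctc = 6)
  w <- slit_transmission_weights(0, 3, coll)
  # independent numerical integration oracle
  oracle <- vapply(w$x1_mm, function(x1) {
    stats::integrate(function(x) dnorm(x, 0, 3), x1 - 0.2, x1 + 0.2)$value
  }, numeric(1))
  expect_equal(w$weight, oracle, tolerance = 1e-6)
  # symmetric about the aligned slit, non-negative, bounded by the open area
  expect_equal(w$weight, rev(w$weight))
  expect_true(all(w$weight >= 0))
  expect_lt(sum(w$weight), 1)
})

test_that("a vanishing spot width concentrates on the containing slit", {
  coll <- pmbrt_collimator(ctc = 6)
  w <- slit_transmission_weights(6, 1e-4, coll)
  expect_equal(w$weight[w$x1_mm == 6], 1, tolerance = 1e-9)
  expect_equal(sum(w$weight), 1, tolerance = 1e-9)
})
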