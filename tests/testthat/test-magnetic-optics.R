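test_that("straight-drift landing follows the tilt and range", {
  expect_equal(reference_landing_x(0, 100, model = rm_tab), 0)
  # 65 + 70 + 77.18 mm drift at 0.1 deg
  expect_equal(reference_landing_x(4, 100, model = rm_tab), 4.3703,
               tolerance = 1e-4)
  expect_equal(reference_landing_x(28, 100, model = rm_tab), 30.592,
               tolerance = 1e-4)
})

test_that("dipole exit angle matches the Larmor kick closed form", {
  expect_equal(dipole_exit_angle(0.01, 0, 100), 0.01)
  theta <- 0.15 * pi / 180
  expect_equal(dipole_exit_angle(theta, 1, 100, 50),
               theta - asin(0.05 / magnetic_rigidity(100)),
               tolerance = 1e-6)
  # Larmor radius not larger than the dipole: infeasible
  expect_error(dipole_exit_angle(0, 40, 100, 50),
               class = "minibeamr_infeasible_deflection")
})

test_that("dipole landing reduces to the straight-drift equation at B = 0", {
  c6 <- pmbrt_collimator(ctc = 6)
  for (E in c(100, 150)) {
    expect_equal(dipole_landing_x(6, 0, E, c6, model = rm_tab),
                 reference_landing_x(6, E, c6, model = rm_tab),
                 tolerance = 1e-9)
  }
})

test_that("increasing dipole field strictly decreases the landing position", {
  c6 <- pmbrt_collimator(ctc = 6)
  x2 <- vapply(seq(0, 2, by = 0.25), function(b) {
    dipole_landing_x(12, b, 150, c6, model = rm_tab)
  }, numeric(1))
  expect_true(all(diff(x2) < 0))
})

test_that("zero-field trajectories are straight and end at the range", {
  tr <- integrate_trajectory(5, 0, 0, 100, model = rm_tab)
  expect_equal(attr(tr, "end_z"), range_in_water(100, rm_tab), tolerance = 1e-9)
  expect_equal(attr(tr, "landing_x"), 5, tolerance = 1e-9)
  # small tilt: landing x = entry + depth * tan(angle)
  a <- 0.01
  tr2 <- integrate_trajectory(0, a, 0, 100, model = rm_tab)
  expect_equal(attr(tr2, "landing_x"),
               attr(tr2, "end_z") * tan(a), tolerance = 1e-9)
  expect_true(all(diff(tr2$z_mm) > 0))
  expect_gte(attr(tr2, "path_length"), attr(tr2, "end_z"))
})

test_that("the integrator is converged at the default step", {
  B <- solve_phantom_field(42, 100, reference_landing_x(28, 100, model = rm_tab),
                           pmbrt_collimator(ctc = 6), model = rm_tab)
  l1 <- phantom_landing_x(42, B, 100, pmbrt_collimator(ctc = 6), model = rm_tab,
                          step = 0.1)
  l2 <- phantom_landing_x(42, B, 100, pmbrt_collimator(ctc = 6), model = rm_tab,
                          step = 0.05)
  expect_lt(abs(l1 - l2), 1e-4) # < 0.1 micron
})

test_that("closed-form dipole kick agrees with in-dipole RK4 tracking", {
  # constant-energy tracking across the dipole; r >= 20 * dz throughout
  for (theta in c(0, 0.15, 1.05) * pi / 180) {
    for (B in c(0.3, 0.8, 1.4)) {
      tr <- integrate_trajectory(0, theta, B, 100, stop = "at-path",
                                 depth = 50, slowing = FALSE, model = rm_tab,
                                 step = 0.1)
      kick_rk <- theta - tr$angle_rad[nrow(tr)]
      kick_cf <- theta - dipole_exit_angle(theta, B, 100, 50)
      expect_lt(abs(kick_cf / kick_rk - 1), 1e-3)
    }
  }
})

test_that("field solvers close the loop on the target landing position", {
  c6 <- pmbrt_collimator(ctc = 6)
  # dipole: reconstruct a known field from its own landing
  b_true <- 0.8
  target <- dipole_landing_x(18, b_true, 150, c6, model = rm_tab)
  expect_equal(solve_dipole_field(18, 150, target, c6, model = rm_tab), b_true,
               tolerance = 1e-5)
  # zero-field target returns B = 0
  expect_equal(
    solve_dipole_field(6, 150, reference_landing_x(6, 150, c6, model = rm_tab),
                       c6, model = rm_tab),
    0, tolerance = 1e-6)
  # phantom: solved field lands within 1 micron of the target
  target3 <- reference_landing_x(4, 150, model = rm_tab)
  b3 <- solve_phantom_field(6, 150, target3, c6, model = rm_tab)
  expect_lt(abs(phantom_landing_x(6, b3, 150, c6, model = rm_tab) - target3),
            1e-3)
  # mirror slit needs the same magnitude
  b3m <- solve_phantom_field(-6, 150, -target3, c6, model = rm_tab)
  expect_equal(b3m, b3, tolerance = 1e-6)
  # unreachable target reports the achievable landing window
  expect_error(solve_dipole_field(6, 150, 60, c6, model = rm_tab),
               class = "minibeamr_infeasible_target")
})

test_that("field tables satisfy the monotonicity and linearity structure", {
  s3 <- make_scenario("config3")
  ft <- build_field_table(s3, c(100, 150), rm_tab)
  expect_s3_class(ft, "field_table")
  expect_equal(nrow(ft), 14)
  expect_named(as_tibble(ft),
               c("configuration", "slit_offset_mm", "energy_MeV", "field_T"))
  for (e in c(100, 150)) {
    b <- ft$field_T[ft$energy_MeV == e]
    expect_true(all(diff(b) > 0)) # grows with off-axis distance
  }
  for (k in unique(ft$slit_offset_mm)) {
    b <- ft$field_T[ft$slit_offset_mm == k]
    expect_true(all(diff(b) < 0)) # falls with energy
  }
  # small-angle linearity: B(12 mm) / B(6 mm) = 2 within 1%
  b6 <- ft$field_T[ft$slit_offset_mm == 6 & ft$energy_MeV == 150]
  b12 <- ft$field_T[ft$slit_offset_mm == 12 & ft$energy_MeV == 150]
  expect_equal(b12 / b6, 2, tolerance = 0.01)
  # empty energy list gives an empty table
  expect_equal(nrow(build_field_table(s3, numeric(0), rm_tab)), 0)
  # no-field scenario has nothing to optimize
  expect_error(build_field_table(make_scenario("config1"), 100, rm_tab),
               class = "minibeamr_config_error")
})

test_that("spot field lookup signs the deflection towards the axis", {
  s3 <- make_scenario("config3")
  ft <- build_field_table(s3, 150, rm_tab)
  b <- field_for_spot(ft, 12, 150)
  expect_gt(b, 0)
  expect_equal(field_for_spot(ft, -12, 150), -b)
  expect_equal(field_for_spot(ft, 0, 150), 0)
  expect_error(field_for_spot(ft, 12, 100), class = "minibeamr_config_error")
})
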