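test_that("relativistic momentum matches the closed form", {
  expect_equal(momentum_from_energy(0), 0)
  expect_equal(momentum_from_energy(100), 444.58, tolerance = 1e-4)
  expect_equal(momentum_from_energy(150), 551.35, tolerance = 1e-4)
  expect_error(momentum_from_energy(-1), class = "minibeamr_domain_error")
})

test_that("magnetic rigidity and the Larmor radius follow p/q", {
  expect_equal(magnetic_rigidity(100), 1.483, tolerance = 1e-3)
  expect_equal(magnetic_rigidity(150), 1.839, tolerance = 1e-3)
  # Larmor radius at 1 T equals the rigidity
  expect_equal(magnetic_rigidity(100) / 1, 1.483, tolerance = 1e-3)
  expect_error(magnetic_rigidity(0), class = "minibeamr_domain_error")
})

test_that("momentum and rigidity are strictly increasing in energy", {
  e <- 1:230
  expect_true(all(diff(momentum_from_energy(e)) > 0))
  expect_true(all(diff(magnetic_rigidity(e)) > 0))
})

test_that("water ranges agree with CSDA reference values in both modes", {
  for (m in list(rm_pow, rm_tab)) {
    expect_equal(range_in_water(0, m), 0)
    expect_equal(range_in_water(100, m), 77.18, tolerance = 0.02)
    expect_equal(range_in_water(150, m), 157.7, tolerance = 0.02)
    expect_error(range_in_water(231, m), class = "minibeamr_domain_error")
  }
})

test_that("power-law and tabulated range modes agree within 2% on 70-230 MeV", {
  e <- seq(70, 230, by = 1)
  rel <- abs(range_in_water(e, rm_pow) / range_in_water(e, rm_tab) - 1)
  expect_lt(max(rel), 0.02)
})

test_that("energy-range round trip inverts to 0.1% in both modes", {
  e <- seq(10, 230, by = 2)
  for (m in list(rm_pow, rm_tab)) {
    back <- energy_from_residual_range(range_in_water(e, m), m)
    expect_lt(max(abs(back - e) / e), 1e-3)
    expect_equal(energy_from_residual_range(0, m), 0, tolerance = 1e-6)
  }
  # monotone between samples: half range maps into (0, E)
  half <- energy_from_residual_range(range_in_water(150, rm_tab) / 2, rm_tab)
  expect_true(half > 0 && half < 150)
  expect_error(energy_from_residual_range(-1), class = "minibeamr_domain_error")
})

test_that("range straggling grows with energy and stays positive", {
  s <- range_straggling_sigma(c(100, 150), rm_tab)
  expect_true(all(s > 0))
  expect_gt(s[2], s[1])
})

test_that("Highland angle matches a direct evaluation and vanishes with step", {
  # independent hand evaluation at 150 MeV, 10 mm water
  p <- sqrt(150 * (150 + 2 * 938.272))
  beta <- p / (150 + 938.272)
  t <- 10 / 360.8
  expect_equal(highland_sigma_theta(150, 10),
               14.1 / (p * beta) * sqrt(t) * (1 + log10(t) / 9),
               tolerance = 1e-12)
  expect_lt(highland_sigma_theta(150, 1e-4), 1e-4)
  expect_error(highland_sigma_theta(150, 0), class = "minibeamr_domain_error")
})
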