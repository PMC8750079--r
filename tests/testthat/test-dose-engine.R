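test_that("the analytical Bragg curve peaks near the range and then vanishes", {
  z <- seq(0, 200, by = 0.05)
  for (E in c(100, 150)) {
    b <- bragg_depth_dose(E, z, rm_tab)
    r0 <- range_in_water(E, rm_tab)
    # peak within ~one straggling sigma upstream of the CSDA range
    expect_lt(abs(z[which.max(b)] - r0), 1.5)
    expect_equal(max(b), 1)
    expect_lt(b[1], max(b)) # entrance below peak
    expect_equal(bragg_depth_dose(E, r0 + 30, rm_tab), 0)
  }
  expect_error(bragg_depth_dose(150, -1), class = "minibeamr_domain_error")
})

test_that("lateral spread accumulates Fermi-Eyges moments of Highland power", {
  expect_equal(lateral_sigma(150, 0, sigma0 = 0.2, model = rm_tab), 0.2)
  z <- seq(0, 150, by = 10)
  s <- lateral_sigma(150, z, model = rm_tab)
  expect_true(all(diff(s) >= 0))
  # independent adaptive-quadrature oracle
  fe_oracle <- function(E, zz, sigma0 = 0.2) {
    r0 <- range_in_water(E, rm_tab)
    t_fun <- function(u) {
      e <- energy_from_residual_range(pmax(r0 - u, 0.05), rm_tab)
      p <- momentum_from_energy(e)
      pv <- p * p / (e + 938.272)
      (14.1 / pv)^2 / 360.8
    }
    a2 <- stats::integrate(function(u) (zz - u)^2 * t_fun(u), 0, zz,
                           rel.tol = 1e-9)$value
    sqrt(sigma0^2 + a2)
  }
  for (zz in c(30, 70, 120)) {
    expect_equal(lateral_sigma(150, zz, model = rm_tab), fe_oracle(150, zz),
                 tolerance = 0.01)
  }
  expect_error(lateral_sigma(150, 200, model = rm_tab),
               class = "minibeamr_domain_error")
})

test_that("a degenerate single-slit scenario yields one normalized ridge", {
  sc <- make_fixtures("single-slit-scenario")
  d <- compute_dose(sc, 100, model = rm_tab)
  p <- transverse_profile(d, 40)
  # exactly one ridge
  pk <- which(diff(sign(diff(p$dose))) < 0) + 1
  pk <- pk[p$dose[pk] > 0.5 * max(p$dose)]
  expect_equal(length(pk), 1)
  expect_lt(abs(p$x_mm[pk]), 0.2)
  # transverse integral at depth z equals total flux times the depth dose
  flux <- sum(vapply(seq(-15, 15) * 4, function(sx) {
    w <- slit_transmission_weights(sx, 3, sc$collimator)
    sum(w$weight)
  }, numeric(1)))
  j <- which.min(abs(d$z_mm - 40))
  got <- sum(d$values[, , j]) * d$voxel_mm[1] * d$voxel_mm[2]
  want <- flux * bragg_depth_dose(100, d$z_mm[j], rm_tab,
                                  energy_spread = 0.01)
  expect_equal(got, want, tolerance = 1e-3)
})

test_that("zero spot weights give a zero grid", {
  s1 <- make_scenario("config1")
  d <- compute_dose(s1, 100, model = rm_tab,
                    spot_weights = rep(0, 31))
  expect_equal(max(abs(d$values)), 0)
  expect_equal(dim(d$values), c(500, 10, 150))
})

test_that("the reference pattern carries 15 mirror-symmetric ridges on the predicted axes", {
  d1 <- e2e_grids_150()$d1
  p <- transverse_profile(d1, 70)
  pk <- which(diff(sign(diff(p$dose))) < 0) + 1
  pk <- pk[p$dose[pk] > 0.2 * max(p$dose)]
  expect_equal(length(pk), 15)
  # ridge positions match the straight-drift axes at this depth
  sl <- slit_positions(pmbrt_collimator())
  want <- sl$x1_mm + (65 + 70 + 70) * tan(sl$tilt_rad)
  expect_lt(max(abs(sort(p$x_mm[pk]) - sort(want))), 0.25)
  # mirror symmetry of the slice within 1%
  expect_lt(max(abs(p$dose - rev(p$dose))) / max(p$dose), 0.01)
})

test_that("a static collimator with a dipole broadens minibeams; a dynamic aperture does not", {
  s2 <- make_scenario("config2")
  s2p <- make_scenario("config2p")
  ft <- build_field_table(s2, 150, rm_tab)
  d1 <- e2e_grids_150()$d1
  d2 <- compute_dose(s2, 150, ft, model = rm_tab)
  d2p <- compute_dose(s2p, 150, ft, model = rm_tab)
  fwhm <- function(d) {
    p <- transverse_profile(d, 70)
    sel <- abs(p$x_mm) < 3
    x <- p$x_mm[sel]; v <- p$dose[sel]
    im <- which.max(v); half <- v[im] / 2
    xl <- approx(v[1:im], x[1:im], half)$y
    xr <- approx(rev(v[im:length(v)]), rev(x[im:length(v)]), half)$y
    xr - xl
  }
  w1 <- fwhm(d1); w2 <- fwhm(d2); w2p <- fwhm(d2p)
  expect_gt(w2, w2p)            # broadening from non-optimized deflection
  expect_lt(abs(w1 - w2p) / w1, 0.10) # dynamic aperture matches the reference
})
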