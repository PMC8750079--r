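#' Reference (no-field) landing position at the Bragg peak
#'
#' Straight-drift landing of a minibeam central axis:
#' `x2 = x1 + (dz_coll + dz_air + R(E)) * tan(theta(x1))`, with theta the
#' slit tilt, dz_coll the collimator thickness, dz_air the air gap and R(E)
#' the proton range in water.
#'
#' @param x1_mm Slit off-axis distance in mm (vectorised).
#' @param energy_mev Beam kinetic energy in MeV.
#' @param collimator A [pmbrt_collimator()]; supplies the tilt gradient and
#'   thickness.
#' @param air_gap Collimator rear surface to phantom entrance, mm.
#' @param model A [range_model()].
#' @return Landing x coordinate `x2` in mm at the Bragg peak depth.
#' @export
reference_landing_x <- function(x1_mm, energy_mev,
                                collimator = pmbrt_collimator(),
                                air_gap = 70, model = range_model()) {
  theta <- slit_tilt_rad(x1_mm, collimator)
  drift <- collimator$thickness + air_gap + range_in_water(energy_mev, model)
  x1_mm + drift * tan(theta)
}

#' Exit angle of a minibeam deflected by a thin dipole
#'
#' Larmor-radius kick: `phi = theta - asin(dz_dip / r)` with
#' `r = rigidity(E) / B`. Signed fields are supported: a positive field (along
#' +y) bends a proton travelling along +z towards -x.
#'
#' @param theta Entry angle to the beamline axis, radians.
#' @param field_t Dipole field in tesla (signed; 0 returns `theta`).
#' @param energy_mev Kinetic energy in MeV.
#' @param dipole_thickness Dipole length along z in mm.
#' @return Exit angle phi in radians.
#' @export
dipole_exit_angle <- function(theta, field_t, energy_mev, dipole_thickness = 50) {
  if (all(field_t == 0)) return(theta)
  rigidity_mm <- magnetic_rigidity(energy_mev) * 1000
  s <- dipole_thickness * field_t / rigidity_mm # = dz_dip / r, signed
  if (any(abs(s) >= 1)) {
    abort("Infeasible deflection: Larmor radius not larger than the dipole thickness.",
          class = "minibeamr_infeasible_deflection")
  }
  theta - asin(s)
}

#' Landing position of a dipole-deflected minibeam
#'
#' Straight segments through the collimator and dipole along the slit tilt,
#' the Larmor kick of [dipole_exit_angle()], then a straight drift to the
#' Bragg peak. The drift convention is selectable:
#' * `"air+range"` (default): drift along the exit angle covers the air
#'   remaining after the dipole plus the in-water range, so the zero-field
#'   limit reproduces [reference_landing_x()];
#' * `"range-only"`: drift of `R(E)` from the dipole exit, with the lateral
#'   displacement inside the dipole neglected (`x_de = x1`);
#' * `"dipole-center"`: drift measured from the dipole mid-plane.
#'
#' @inheritParams reference_landing_x
#' @param field_t Dipole field in tesla (signed).
#' @param dipole_thickness Dipole length in mm.
#' @param drift Drift convention, see Details.
#' @return Landing x coordinate `x2` in mm.
#' @export
dipole_landing_x <- function(x1_mm, field_t, energy_mev,
                             collimator = pmbrt_collimator(ctc = 6),
                             air_gap = 70, dipole_thickness = 50,
                             drift = c("air+range", "range-only", "dipole-center"),
                             model = range_model()) {
  drift <- match.arg(drift)
  theta <- slit_tilt_rad(x1_mm, collimator)
  phi <- dipole_exit_angle(theta, field_t, energy_mev, dipole_thickness)
  r_mm <- range_in_water(energy_mev, model)
  switch(drift,
    "air+range" = {
      xde <- x1_mm + (collimator$thickness + dipole_thickness) * tan(theta)
      xde + (air_gap - dipole_thickness + r_mm) * tan(phi)
    },
    "range-only" = x1_mm + r_mm * tan(phi),
    "dipole-center" = {
      xde <- x1_mm + (collimator$thickness + dipole_thickness / 2) * tan(theta)
      xde + (dipole_thickness / 2 + air_gap - dipole_thickness + r_mm) * tan(phi)
    }
  )
}

# Fast curvature lookup 1/(B rho) [1/(T mm)] as a function of arc length s
# (mm) for a proton of initial energy E slowing down in water. The lookup is
# built once per (energy, model) and shared across solver iterations.
curvature_fun <- function(energy_mev, model = range_model(), slowing = TRUE) {
  if (!slowing) {
    k0 <- 1 / (magnetic_rigidity(energy_mev) * 1000)
    return(function(s) rep_len(k0, length(s)))
  }
  r_total <- range_in_water(energy_mev, model)
  inv <- inverse_range_fun(model)
  # finer sampling near the end of range where the curvature grows
  s_grid <- unique(c(seq(0, max(r_total - 2, 0), by = 0.25),
                     seq(max(r_total - 2, 0), r_total - 0.01, by = 0.005),
                     r_total - 0.01))
  rres <- pmax(r_total - s_grid, 0.01)
  e <- inv(rres)
  kappa <- MEV_PER_TESLA_M / (1000 * momentum_from_energy(e))
  approxfun(s_grid, kappa, rule = 2)
}

#' Track a minibeam central axis through a uniform magnetic field
#'
#' Integrates the planar equations of motion of a proton slowing down in
#' water inside a uniform field along +y,
#' `dx/ds = sin(alpha)`, `dz/ds = cos(alpha)`, `dalpha/ds = -B / Brho(s)`,
#' with the rigidity evaluated at the residual range `R(E) - s` along the arc
#' length s. Classical 4th-order Runge-Kutta with a fixed arc-length step and
#' a fine-step tail (0.01 mm) over the last 2 mm of range, where the
#' curvature varies fastest.
#'
#' @param entry_x Entry x coordinate at the phantom surface (z = 0), mm.
#' @param entry_angle Entry angle to the z axis, radians.
#' @param field_t Uniform field in tesla (signed; positive bends towards -x).
#' @param energy_mev Kinetic energy at entry, MeV.
#' @param stop `"at-range"` (terminate when the path length equals R(E)),
#'   `"at-depth"` (terminate at depth `depth` or at range, whichever first) or
#'   `"at-path"` (terminate at path length `depth`).
#' @param depth Stop depth (or path length) in mm for `stop = "at-depth"` /
#'   `"at-path"`.
#' @param step Nominal arc-length step in mm (default 0.1).
#' @param model A [range_model()].
#' @param slowing If `FALSE`, integrate at constant energy (tracking inside a
#'   dipole gap rather than in water).
#' @param x_bounds Lateral phantom bounds in mm; exceeding them raises an
#'   out-of-bounds error carrying the partial trajectory.
#' @param .kappa Internal: precomputed curvature lookup (shared across solver
#'   iterations).
#' @return A `trajectory`: a tibble with columns `s_mm` (path length), `z_mm`,
#'   `x_mm`, `angle_rad`, and attributes `entry_x`, `landing_x`, `end_z`,
#'   `path_length`.
#' @export
integrate_trajectory <- function(entry_x, entry_angle, field_t, energy_mev,
                                 stop = c("at-range", "at-depth", "at-path"),
                                 depth = NULL,
                                 step = 0.1, model = range_model(),
                                 slowing = TRUE, x_bounds = c(-50, 50),
                                 .kappa = NULL) {
  stop_mode <- match.arg(stop)
  if (energy_mev <= 0 || energy_mev > E_MAX_MEV) {
    abort("`energy_mev` out of model bounds.", class = "minibeamr_domain_error")
  }
  if (stop_mode != "at-range" && is.null(depth)) {
    abort("`depth` is required for stop = \"at-depth\" / \"at-path\".",
          class = "minibeamr_config_error")
  }
  if (!slowing && stop_mode == "at-range") {
    abort("stop = \"at-range\" requires a slowing-down medium.",
          class = "minibeamr_config_error")
  }
  kappa <- .kappa %||% curvature_fun(energy_mev, model, slowing = slowing)
  r_total <- if (slowing) range_in_water(energy_mev, model) else Inf
  s_end <- switch(stop_mode,
    "at-range" = r_total,
    "at-path" = min(depth, r_total),
    "at-depth" = min(depth / cos(entry_angle) * 2 + 10, r_total))

  # step schedule: uniform body + fine tail over the last 2 mm of range
  tail_len <- if (slowing) min(2, s_end) else 0
  body_len <- s_end - tail_len
  n_body <- max(ceiling(body_len / step), 0)
  h_body <- if (n_body > 0) body_len / n_body else 0
  h <- c(rep(h_body, n_body), rep(0.01, ceiling(tail_len / 0.01)))
  # trim so total equals s_end
  cum <- cumsum(h)
  h <- h[cum <= s_end + 1e-12]
  if ((rem <- s_end - sum(h)) > 1e-12) h <- c(h, rem)

  n <- length(h)
  out_s <- numeric(n + 1); out_z <- numeric(n + 1)
  out_x <- numeric(n + 1); out_a <- numeric(n + 1)
  x <- entry_x; z <- 0; a <- entry_angle; s <- 0
  out_x[1] <- x; out_z[1] <- z; out_a[1] <- a; out_s[1] <- s
  B <- field_t
  i_last <- n + 1
  for (i in seq_len(n)) {
    hi <- h[i]
    k1 <- c(sin(a), cos(a), -B * kappa(s))
    a2 <- a + hi / 2 * k1[3]
    k2 <- c(sin(a2), cos(a2), -B * kappa(s + hi / 2))
    a3 <- a + hi / 2 * k2[3]
    k3 <- c(sin(a3), cos(a3), -B * kappa(s + hi / 2))
    a4 <- a + hi * k3[3]
    k4 <- c(sin(a4), cos(a4), -B * kappa(s + hi))
    incr <- hi / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    x <- x + incr[1]; z <- z + incr[2]; a <- a + incr[3]; s <- s + hi
    out_x[i + 1] <- x; out_z[i + 1] <- z; out_a[i + 1] <- a; out_s[i + 1] <- s
    if (x < x_bounds[1] || x > x_bounds[2]) {
      partial <- new_trajectory(out_s[1:(i + 1)], out_z[1:(i + 1)],
                                out_x[1:(i + 1)], out_a[1:(i + 1)], entry_x)
      abort("Trajectory exited the phantom laterally.",
            class = "minibeamr_out_of_bounds", trajectory = partial)
    }
    if (stop_mode == "at-depth" && z >= depth) { i_last <- i + 1; break }
  }
  idx <- seq_len(min(i_last, n + 1))
  new_trajectory(out_s[idx], out_z[idx], out_x[idx], out_a[idx], entry_x)
}

new_trajectory <- function(s, z, x, a, entry_x) {
  tr <- tibble(s_mm = s, z_mm = z, x_mm = x, angle_rad = a)
  structure(tr,
            class = c("trajectory", class(tr)),
            entry_x = entry_x,
            landing_x = x[length(x)],
            end_z = z[length(z)],
            path_length = s[length(s)])
}

#' Landing position of a minibeam curved inside the phantom
#'
#' Convenience wrapper over [integrate_trajectory()]: drifts the slit axis
#' through the collimator and air gap, then integrates the slowing-down
#' trajectory in the in-phantom field to the end of range.
#' @inheritParams dipole_landing_x
#' @param step RK4 arc-length step in mm.
#' @param .kappa Internal: precomputed curvature lookup.
#' @return Landing x coordinate in mm at end of range.
#' @export
phantom_landing_x <- function(x1_mm, field_t, energy_mev,
                              collimator = pmbrt_collimator(ctc = 6),
                              air_gap = 70, model = range_model(),
                              step = 0.1, .kappa = NULL) {
  theta <- slit_tilt_rad(x1_mm, collimator)
  entry_x <- x1_mm + (collimator$thickness + air_gap) * tan(theta)
  tr <- integrate_trajectory(entry_x, theta, field_t, energy_mev,
                             stop = "at-range", step = step, model = model,
                             .kappa = .kappa)
  attr(tr, "landing_x")
}

solve_field <- function(landing_fn, target_x2, bracket = c(0, 10),
                        tol_mm = 1e-3) {
  f <- function(b) landing_fn(b) - target_x2
  f_lo <- f(bracket[1]); f_hi <- f(bracket[2])
  if (sign(f_lo) == sign(f_hi)) {
    abort(sprintf(
      "Infeasible target: achievable landing range is [%.3f, %.3f] mm for fields in [%g, %g] T.",
      min(f_lo, f_hi) + target_x2, max(f_lo, f_hi) + target_x2,
      bracket[1], bracket[2]),
      class = "minibeamr_infeasible_target")
  }
  root <- uniroot(f, bracket, f.lower = f_lo, f.upper = f_hi, tol = 1e-8)
  if (abs(f(root$root)) > tol_mm) {
    abort("Field solver did not reach the landing tolerance.",
          class = "minibeamr_solver_error")
  }
  root$root
}

#' Solve the dipole field converging a slit onto a target landing position
#'
#' Brent root of `dipole_landing_x(B) = target_x2` for B in `bracket` (tesla),
#' to better than `tol_mm` on the landing position. Slits at negative
#' off-axis distance require the same magnitude with the opposite sign; the
#' returned value is the (positive) magnitude for `x1_mm >= 0`.
#'
#' @inheritParams dipole_landing_x
#' @param target_x2 Target landing x coordinate in mm.
#' @param bracket Field search interval in tesla.
#' @param tol_mm Landing tolerance in mm (default 1e-3, i.e. 1 micron).
#' @return Field strength in tesla.
#' @export
solve_dipole_field <- function(x1_mm, energy_mev, target_x2,
                               collimator = pmbrt_collimator(ctc = 6),
                               air_gap = 70, dipole_thickness = 50,
                               drift = "air+range", model = range_model(),
                               bracket = c(0, 10), tol_mm = 1e-3) {
  mirror <- x1_mm < 0
  if (mirror) { x1_mm <- -x1_mm; target_x2 <- -target_x2 }
  b <- solve_field(function(b) {
    dipole_landing_x(x1_mm, b, energy_mev, collimator, air_gap,
                     dipole_thickness, drift = drift, model = model)
  }, target_x2, bracket, tol_mm)
  b
}

#' Solve the in-phantom field converging a slit onto a target landing position
#'
#' Brent root of the RK4-integrated slowing-down landing position over the
#' field strength, `|x2(B) - target| < tol_mm`.
#'
#' @inheritParams phantom_landing_x
#' @inheritParams solve_dipole_field
#' @return Field strength in tesla (magnitude; negative slits mirror).
#' @export
solve_phantom_field <- function(x1_mm, energy_mev, target_x2,
                                collimator = pmbrt_collimator(ctc = 6),
                                air_gap = 70, model = range_model(),
                                step = 0.1, bracket = c(0, 10), tol_mm = 1e-3) {
  mirror <- x1_mm < 0
  if (mirror) { x1_mm <- -x1_mm; target_x2 <- -target_x2 }
  kappa <- curvature_fun(energy_mev, model)
  solve_field(function(b) {
    # a trajectory that curls out of the phantom at large B counts as landing
    # at its exit position: keeps the bracket monotone for the root search
    tryCatch(
      phantom_landing_x(x1_mm, b, energy_mev, collimator, air_gap, model,
                        step = step, .kappa = kappa),
      minibeamr_out_of_bounds = function(e) {
        tr <- e$trajectory
        tr$x_mm[nrow(tr)]
      })
  }, target_x2, bracket, tol_mm)
}

#' Optimized field table for a converging-minibeam scenario
#'
#' One optimized field strength per (positive off-axis slit, energy): the
#' field that makes the enlarged-ctc minibeam land, at its Bragg peak, on the
#' straight-drift landing position of the index-matched slit of the reference
#' (4 mm ctc, no field) collimator. Rows that cannot be solved are returned
#' with `NA` and a warning; remaining rows are still computed.
#'
#' @param scenario A [make_scenario()] with a field region (`config2`,
#'   `config2p`, `config3`, `config3p`).
#' @param energies Beam energies in MeV (may be empty).
#' @param model A [range_model()].
#' @param drift Drift convention for dipole scenarios, see
#'   [dipole_landing_x()].
#' @param step RK4 step for in-phantom scenarios, mm.
#' @return A `field_table` tibble: `configuration`, `slit_offset_mm`,
#'   `energy_MeV`, `field_T`.
#' @export
build_field_table <- function(scenario, energies, model = range_model(),
                              drift = "air+range", step = 0.1) {
  if (scenario$field_region == "none") {
    abort("Scenario has no field region; nothing to optimize.",
          class = "minibeamr_config_error")
  }
  coll <- scenario$collimator
  ref_coll <- pmbrt_collimator(ctc = scenario$reference_ctc,
                               n_slits = coll$n_slits,
                               tilt_gradient = coll$tilt_gradient,
                               thickness = coll$thickness)
  k <- seq_len((coll$n_slits - 1) / 2)
  rows <- tidyr::expand_grid(slit_offset_mm = k * coll$ctc,
                             energy_MeV = as.numeric(energies))
  if (nrow(rows) == 0) {
    return(new_field_table(tibble(configuration = character(),
                                  slit_offset_mm = numeric(),
                                  energy_MeV = numeric(),
                                  field_T = numeric()), scenario))
  }
  rows$field_T <- purrr::pmap_dbl(rows, function(slit_offset_mm, energy_MeV) {
    ref_x1 <- slit_offset_mm / coll$ctc * scenario$reference_ctc
    target <- reference_landing_x(ref_x1, energy_MeV, ref_coll,
                                  scenario$air_gap, model)
    tryCatch({
      if (scenario$field_region == "dipole") {
        solve_dipole_field(slit_offset_mm, energy_MeV, target, coll,
                           scenario$air_gap, scenario$dipole_thickness,
                           drift = drift, model = model)
      } else {
        solve_phantom_field(slit_offset_mm, energy_MeV, target, coll,
                            scenario$air_gap, model, step = step)
      }
    }, minibeamr_infeasible_target = function(e) {
      warn(sprintf("Slit %g mm at %g MeV: %s", slit_offset_mm, energy_MeV,
                   conditionMessage(e)))
      NA_real_
    })
  })
  out <- dplyr::bind_cols(tibble(configuration = scenario$name), rows)
  new_field_table(out, scenario)
}

new_field_table <- function(df, scenario = NULL) {
  structure(df, class = c("field_table", class(tibble())),
            scenario_name = if (!is.null(scenario)) scenario$name else NULL)
}

#' Look up the signed field for a pencil-beam spot
#'
#' The field is correlated with the spot x coordinate: magnitude from the
#' field table row at the matching off-axis distance, sign chosen so the
#' deflection points towards the axis (zero on axis and for absent rows in
#' no-field scenarios).
#'
#' @param field_table A [build_field_table()] result.
#' @param spot_x Spot x coordinate in mm.
#' @param energy_mev Energy layer in MeV.
#' @param extrapolate Spots beyond the outermost optimized slit (the spot
#'   grid is wider than the collimator) get a proportionally extrapolated
#'   field, consistent with the near-linear field-versus-offset correlation;
#'   `FALSE` raises instead.
#' @return Signed field in tesla.
#' @export
field_for_spot <- function(field_table, spot_x, energy_mev,
                           extrapolate = TRUE) {
  if (spot_x == 0) return(0)
  at_e <- dplyr::filter(field_table,
                        abs(.data$energy_MeV - energy_mev) < 1e-9,
                        !is.na(.data$field_T))
  row <- dplyr::filter(at_e, abs(.data$slit_offset_mm - abs(spot_x)) < 1e-9)
  if (nrow(row) == 1) return(row$field_T * sign(spot_x))
  if (extrapolate && nrow(at_e) > 0 &&
      abs(spot_x) > max(at_e$slit_offset_mm)) {
    outer_row <- dplyr::slice_max(at_e, .data$slit_offset_mm, n = 1)
    return(outer_row$field_T * abs(spot_x) / outer_row$slit_offset_mm *
             sign(spot_x))
  }
  abort(sprintf("No optimized field for slit offset %g mm at %g MeV.",
                abs(spot_x), energy_mev),
        class = "minibeamr_config_error")
}
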