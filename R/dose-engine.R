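# Bortfeld-style analytical Bragg curve parameters: fluence-reduction slope
# (per mm), dose fraction deposited by non-elastic nuclear products, and the
# fraction of primary fluence in the low-energy spectrum tail.
BRAGG_BETA_MM <- 0.0012
BRAGG_GAMMA <- 0.6
BRAGG_EPSILON <- 0.2

# Combined Gaussian range-broadening sigma: range straggling plus the range
# spread induced by a relative beam energy spread dE/E.
bragg_sigma_mm <- function(energy_mev, model = range_model(),
                           energy_spread = 0) {
  sig <- range_straggling_sigma(energy_mev, model)
  if (energy_spread > 0) {
    de <- energy_spread * energy_mev
    drde <- (range_in_water(energy_mev, model) -
             range_in_water(energy_mev - 1, model)) # mm/MeV, local slope
    sig <- sqrt(sig^2 + (de * drde)^2)
  }
  sig
}

# Builds a fast lookup for the broadened Bragg curve of one energy,
# normalized to unit peak dose. Cell-averaged power-law terms tame the
# (R - z)^(1/p - 1) singularity before Gaussian convolution.
bragg_curve_fun <- function(energy_mev, model = range_model(), sigma = NULL,
                            energy_spread = 0, dz = 0.1) {
  r0 <- range_in_water(energy_mev, model)
  p <- model$p %||% 1.77
  if (is.null(sigma)) sigma <- bragg_sigma_mm(energy_mev, model, energy_spread)
  z_hi <- r0 + 5 * sigma + 2
  edges <- seq(0, z_hi, by = dz)
  zl <- pmin(edges[-length(edges)], r0)
  zr <- pmin(edges[-1], r0)
  # cell averages of (R - z)^c over [zl, zr]: ((R-zl)^(c+1) - (R-zr)^(c+1)) /
  # ((c+1) dz); zero where the cell lies beyond R
  cell_avg <- function(cc) {
    ((r0 - zl)^(cc + 1) - (r0 - zr)^(cc + 1)) / ((cc + 1) * dz)
  }
  d0 <- cell_avg(1 / p - 1) +
    (BRAGG_BETA_MM * (1 + BRAGG_GAMMA * p) + BRAGG_EPSILON * p / r0) *
      cell_avg(1 / p)
  # discrete Gaussian kernel, same grid
  m <- ceiling(4 * sigma / dz)
  kern <- dnorm(seq(-m, m) * dz, sd = sigma)
  kern <- kern / sum(kern)
  d <- stats::filter(c(rep(d0[1], m), d0, rep(0, m)), kern, sides = 2)
  d <- as.numeric(d)[(m + 1):(m + length(d0))]
  d <- d / max(d)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  approxfun(centers, d, yleft = d[1], yright = 0)
}

#' Analytical Bragg depth-dose curve
#'
#' Power-law (Bragg-Kleeman) stopping power with a linear fluence-reduction
#' term, Gaussian-broadened by range straggling (and optionally by a beam
#' energy spread), normalized to unit peak dose. The peak lies at the CSDA
#' range R(E) to within about a voxel; the dose vanishes beyond the distal
#' falloff.
#'
#' @param energy_mev Kinetic energy in MeV.
#' @param z_mm Depths in mm (vectorised, `>= 0`).
#' @param model A [range_model()].
#' @param sigma Gaussian broadening sigma in mm; default
#'   `range_straggling_sigma(energy_mev)` combined with `energy_spread`.
#' @param energy_spread Relative beam energy spread dE/E (default 0).
#' @return Relative dose (peak = 1).
#' @export
bragg_depth_dose <- function(energy_mev, z_mm, model = range_model(),
                             sigma = NULL, energy_spread = 0) {
  if (any(z_mm < 0)) {
    abort("`z_mm` must be non-negative.", class = "minibeamr_domain_error")
  }
  bragg_curve_fun(energy_mev, model, sigma, energy_spread)(z_mm)
}

#' Lateral beam spread from multiple Coulomb scattering
#'
#' Fermi-Eyges accumulation of the Highland scattering power through water:
#' `sigma^2(z) = sigma0^2 + int_0^z (z - u)^2 T(u) du` with
#' `T(u) = (14.1 / (p v))^2 / X0`, added in quadrature to the source sigma.
#'
#' @param energy_mev Kinetic energy at the phantom surface, MeV.
#' @param z_mm Depth in water, mm (vectorised, in `[0, R(E)]`).
#' @param sigma0 Source (collimator-exit) sigma in mm.
#' @param model A [range_model()].
#' @param step Quadrature step in mm.
#' @return Lateral sigma in mm, non-decreasing in depth.
#' @export
lateral_sigma <- function(energy_mev, z_mm, sigma0 = 0.2,
                          model = range_model(), step = 1) {
  r0 <- range_in_water(energy_mev, model)
  if (any(z_mm < 0) || any(z_mm > r0 + 1e-9)) {
    abort("`z_mm` must lie within [0, R(E)].", class = "minibeamr_domain_error")
  }
  lateral_sigma_fun(energy_mev, sigma0, model, step)(z_mm)
}

# sigma(z) lookup over the full range of one energy
lateral_sigma_fun <- function(energy_mev, sigma0 = 0.2, model = range_model(),
                              step = 1) {
  r0 <- range_in_water(energy_mev, model)
  inv <- inverse_range_fun(model)
  u <- seq(step / 2, max(r0 - step / 2, step / 2), by = step) # midpoints
  e_u <- inv(pmax(r0 - u, 0.05))
  pv <- momentum_from_energy(e_u) * proton_beta(e_u)
  t_u <- (14.1 / pv)^2 / WATER_X0_MM # rad^2 / mm
  zg <- seq(0, r0, length.out = 257)
  a2 <- vapply(zg, function(z) {
    inside <- u < z
    sum((z - u[inside])^2 * t_u[inside]) * step
  }, numeric(1))
  sg <- sqrt(sigma0^2 + a2)
  approxfun(zg, sg, yleft = sigma0, yright = sg[length(sg)])
}

# normalized rectangle (x) Gaussian profile: unit integral over x
rect_gauss <- function(x, center, half_width, sigma) {
  (pnorm((x - center + half_width) / sigma) -
     pnorm((x - center - half_width) / sigma)) / (2 * half_width)
}

# voxel-averaged rectangle (x) Gaussian: exact cell integrals so that narrow
# profiles (sub-voxel sigma near the entrance) conserve their mass on the
# grid. The antiderivative of Phi(t/s) is F(t) = t Phi(t/s) + s phi(t/s);
# deep in the right tail F is dominated by its linear part and naive
# differences cancel catastrophically, so cells whose edges lie entirely
# beyond the rectangle use the tail integral G(t) = s phi(t/s) - t Phi(-t/s)
# (= F(t) - t), whose constant linear offset drops out of the differences.
rect_gauss_cells <- function(centers, dx, center, half_width, sigma) {
  e <- c(centers - dx / 2, centers[length(centers)] + dx / 2) - center
  a <- half_width
  f_fun <- function(t) t * pnorm(t / sigma) + sigma * dnorm(t / sigma)
  g_fun <- function(t) sigma * dnorm(t / sigma) - t * pnorm(-t / sigma)
  n <- length(e)
  right <- (e - a) > 0
  use_g <- right[-n] & right[-1] # both cell edges beyond center + a
  cells <- numeric(n - 1)
  if (any(use_g)) {
    i <- which(use_g)
    s_hi <- g_fun(e[i + 1] + a) - g_fun(e[i + 1] - a)
    s_lo <- g_fun(e[i] + a) - g_fun(e[i] - a)
    cells[i] <- s_hi - s_lo
  }
  if (any(!use_g)) {
    i <- which(!use_g)
    cells[i] <- (f_fun(e[i + 1] + a) - f_fun(e[i + 1] - a)) -
      (f_fun(e[i] + a) - f_fun(e[i] - a))
  }
  pmax(cells, 0) / (2 * a * dx)
}

new_dose_grid <- function(values, x, y, z, voxel, scenario = NULL,
                          energy = NULL) {
  structure(
    list(values = values, x_mm = x, y_mm = y, z_mm = z, voxel_mm = voxel,
         scenario_name = scenario$name %||% NULL,
         ctc = scenario$collimator$ctc %||% NULL,
         energy_mev = energy, units = "relative"),
    class = "dose_grid")
}

#' Construct a dose grid from an array
#'
#' Mostly useful for synthetic fixtures; [compute_dose()] builds grids from a
#' scenario.
#'
#' @param values 3D array indexed (x, y, z).
#' @param x,y,z Voxel-centre coordinates in mm.
#' @return A `dose_grid`.
#' @export
dose_grid <- function(values, x, y, z) {
  stopifnot(length(dim(values)) == 3,
            dim(values)[1] == length(x),
            dim(values)[2] == length(y),
            dim(values)[3] == length(z))
  voxel <- c(if (length(x) > 1) diff(x)[1] else 1,
             if (length(y) > 1) diff(y)[1] else 1,
             if (length(z) > 1) diff(z)[1] else 1)
  new_dose_grid(values, x, y, z, voxel)
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %d x %d x %d voxels (%.2g x %.2g x %.2g mm), %s%s\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3],
              x$scenario_name %||% "fixture",
              if (!is.null(x$energy_mev)) sprintf(", %g MeV", x$energy_mev) else ""))
  invisible(x)
}

#' @export
as_tibble.dose_grid <- function(x, ...) {
  tidyr::expand_grid(z_mm = x$z_mm, y_mm = x$y_mm, x_mm = x$x_mm) |>
    dplyr::mutate(dose = as.vector(x$values)) |>
    dplyr::select("x_mm", "y_mm", "z_mm", "dose")
}

grid_axes <- function(scenario, grid = c("coarse", "full")) {
  grid <- match.arg(grid)
  voxel <- if (grid == "full") scenario$dose_voxels else c(0.2, 10, 2)
  size <- scenario$phantom_size
  axis <- function(extent, v) seq(-extent / 2 + v / 2, extent / 2 - v / 2, by = v)
  list(x = axis(size[1], voxel[1]), y = axis(size[2], voxel[2]),
       z = seq(voxel[3] / 2, size[3] - voxel[3] / 2, by = voxel[3]),
       voxel = voxel)
}

# Central-axis geometry of one beamlet inside the phantom: x position, path
# length and angle sampled at the grid depths.
beamlet_axis <- function(scenario, x1, tilt, field_t, energy_mev, z, model,
                         step = 0.25, .kappa = NULL) {
  coll <- scenario$collimator
  if (scenario$field_region == "dipole" && field_t != 0) {
    phi <- dipole_exit_angle(tilt, field_t, energy_mev,
                             scenario$dipole_thickness)
    entry_x <- x1 + (coll$thickness + scenario$dipole_thickness) * tan(tilt) +
      (scenario$air_gap - scenario$dipole_thickness) * tan(phi)
    list(x = entry_x + z * tan(phi), path = z / cos(phi))
  } else if (scenario$field_region == "phantom" && field_t != 0) {
    entry_x <- x1 + (coll$thickness + scenario$air_gap) * tan(tilt)
    tr <- integrate_trajectory(entry_x, tilt, field_t, energy_mev,
                               stop = "at-range", step = step, model = model,
                               .kappa = .kappa)
    x <- approx(tr$z_mm, tr$x_mm, z, rule = 2)$y
    path <- approx(tr$z_mm, tr$s_mm, z, rule = 2)$y
    # protons at end of range: continue the axis straight along the final
    # direction so the distal falloff is sampled at growing path length
    end_z <- attr(tr, "end_z")
    beyond <- z > end_z
    if (any(beyond)) {
      a_end <- tr$angle_rad[nrow(tr)]
      x[beyond] <- attr(tr, "landing_x") + (z[beyond] - end_z) * tan(a_end)
      path[beyond] <- attr(tr, "path_length") + (z[beyond] - end_z) / cos(a_end)
    }
    list(x = x, path = path)
  } else {
    entry_x <- x1 + (coll$thickness + scenario$air_gap) * tan(tilt)
    list(x = entry_x + z * tan(tilt), path = z / cos(tilt))
  }
}

#' Beamlet-superposition dose computation in the water phantom
#'
#' A desk-scale stand-in for full Monte Carlo transport: every
#' (pencil-beam spot, slit) pair with nonzero transmission emits a beamlet
#' whose central axis is tilted with the slit, kicked by the dipole field
#' assigned to the spot's x coordinate (dipole scenarios) or curved inside
#' the phantom (in-phantom field scenarios). Each beamlet deposits
#' `flux_weight * bragg(path length) * (slit rectangle convolved with the
#' lateral scattering Gaussian)`, uniform over the slit length in y (also
#' convolved). In dynamic-aperture mode each spot feeds exactly one slit, so
#' every beamlet is deflected by its own optimized field and no minibeam
#' broadening occurs.
#'
#' @param scenario A [make_scenario()].
#' @param energy_mev Energy layer in MeV.
#' @param field_table A [build_field_table()] result; required when the
#'   scenario has a field region.
#' @param grid `"coarse"` (0.2 x 10 x 2 mm voxels, default) or `"full"`
#'   (0.1 x 2 x 1 mm).
#' @param sigma0 Collimator-exit beam sigma in mm (default 0.2).
#' @param energy_spread Relative beam energy spread dE/E (default 0.01).
#' @param spot_weights Optional per-spot fluence weights (length `n_x`,
#'   default all 1).
#' @param model A [range_model()].
#' @param step RK4 step for curved axes, mm.
#' @param min_weight Transmission threshold below which a (spot, slit) pair
#'   is skipped.
#' @return A `dose_grid` (values in arbitrary dose per simulated fluence).
#' @export
compute_dose <- function(scenario, energy_mev, field_table = NULL,
                         grid = c("coarse", "full"), sigma0 = 0.2,
                         energy_spread = 0.01, spot_weights = NULL,
                         model = range_model(), step = 0.25,
                         min_weight = 1e-6) {
  ax <- grid_axes(scenario, grid)
  needs_field <- scenario$field_region != "none"
  if (needs_field && is.null(field_table)) {
    abort("`field_table` is required for scenarios with a field region.",
          class = "minibeamr_config_error")
  }
  sg <- scenario$spot_grid
  spots_x <- spot_x_positions(sg)
  if (is.null(spot_weights)) spot_weights <- rep(1, length(spots_x))
  if (length(spot_weights) != length(spots_x)) {
    abort("`spot_weights` must have one weight per spot column.",
          class = "minibeamr_config_error")
  }
  coll <- scenario$collimator
  r0 <- range_in_water(energy_mev, model)
  bragg <- bragg_curve_fun(energy_mev, model, energy_spread = energy_spread)
  sig_fun <- lateral_sigma_fun(energy_mev, sigma0, model)
  kappa <- if (scenario$field_region == "phantom") curvature_fun(energy_mev, model)
  half_w <- coll$slit_width / 2

  # enumerate beamlets: one per (spot, slit) with nonzero transmission
  beamlets <- purrr::imap(spots_x, function(sx, i) {
    if (spot_weights[i] == 0) return(NULL)
    w <- slit_transmission_weights(sx, sg$spot_sigma, coll)
    w <- dplyr::filter(w, .data$weight > min_weight)
    if (nrow(w) == 0) return(NULL)
    b <- if (needs_field) field_for_spot(field_table, sx, energy_mev) else 0
    dplyr::mutate(w, spot_x = sx, field_t = b,
                  flux = .data$weight * spot_weights[i])
  }) |> dplyr::bind_rows()

  n_x <- length(ax$x); n_z <- length(ax$z)
  d2 <- matrix(0, n_x, n_z)
  if (nrow(beamlets) > 0) {
    for (i in seq_len(nrow(beamlets))) {
      bl <- beamlets[i, ]
      tilt <- slit_tilt_rad(bl$x1_mm, coll)
      axis <- beamlet_axis(scenario, bl$x1_mm, tilt, bl$field_t, energy_mev,
                           ax$z, model, step = step, .kappa = kappa)
      depth_dose <- bragg(axis$path)
      live <- which(depth_dose > 0)
      for (j in live) {
        sig <- sig_fun(min(axis$path[j], r0))
        d2[, j] <- d2[, j] + bl$flux * depth_dose[j] *
          rect_gauss_cells(ax$x, ax$voxel[1], axis$x[j], half_w, sig)
      }
    }
  }

  # y profile: slit-length rectangle convolved with the same scattering
  # sigma, shared by all beamlets of the layer (straight-depth approximation)
  half_l <- coll$slit_length / 2
  values <- array(0, c(n_x, length(ax$y), n_z))
  for (j in seq_len(n_z)) {
    sig <- sig_fun(min(ax$z[j], r0))
    py <- rect_gauss_cells(ax$y, ax$voxel[2], 0, half_l, sig)
    values[, , j] <- outer(d2[, j], py)
  }
  new_dose_grid(values, ax$x, ax$y, ax$z, ax$voxel, scenario, energy_mev)
}

#' Sum weighted dose grids
#'
#' @param grids List of `dose_grid`s on identical axes.
#' @param weights Numeric weights, one per grid.
#' @return A `dose_grid`.
#' @export
sum_dose_grids <- function(grids, weights = rep(1, length(grids))) {
  stopifnot(length(grids) >= 1, length(weights) == length(grids))
  out <- grids[[1]]
  values <- out$values * weights[1]
  for (i in seq_along(grids)[-1]) {
    stopifnot(all(dim(grids[[i]]$values) == dim(values)))
    values <- values + grids[[i]]$values * weights[i]
  }
  out$values <- values
  out$energy_mev <- NULL
  out
}

#' Transverse dose profile at a depth
#'
#' Dose averaged over a central y window, sampled at the z slice nearest
#' `depth_mm`.
#'
#' @param dose A `dose_grid`.
#' @param depth_mm Depth in mm.
#' @param y_halfwidth Half-width of the central y averaging window, mm
#'   (default 5, i.e. a 10 mm window through the slit-length plateau).
#' @return A tibble `x_mm`, `dose`.
#' @export
transverse_profile <- function(dose, depth_mm, y_halfwidth = 5) {
  j <- which.min(abs(dose$z_mm - depth_mm))
  sel <- abs(dose$y_mm) <= y_halfwidth
  if (!any(sel)) sel <- which.min(abs(dose$y_mm))
  p <- rowMeans(dose$values[, sel, j, drop = FALSE])
  tibble(x_mm = dose$x_mm, dose = p)
}

#' Central-axis depth-dose series
#'
#' Dose at x = 0 (linear interpolation between the two central voxel
#' columns), averaged over the central y window, per depth.
#'
#' @inheritParams transverse_profile
#' @return A tibble `z_mm`, `dose`.
#' @export
central_axis_depth_dose <- function(dose, y_halfwidth = 5) {
  sel <- abs(dose$y_mm) <= y_halfwidth
  if (!any(sel)) sel <- which.min(abs(dose$y_mm))
  p <- apply(dose$values[, sel, , drop = FALSE], 3,
             function(m) approx(dose$x_mm, rowMeans(m), 0)$y)
  tibble(z_mm = dose$z_mm, dose = p)
}
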