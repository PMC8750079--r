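#' Multislit collimator description
#'
#' The default instance is the reference pMBRT collimator: 15 slits of
#' 0.4 x 45 mm^2, 65 mm thick, centre-to-centre (ctc) distance 4 mm, and a
#' slit tilt increasing linearly with the off-axis distance
#' (0.025 degree/mm) so the slits follow the beam divergence.
#'
#' @param n_slits Odd number of slits (central slit on axis).
#' @param slit_width,slit_length Slit aperture in mm (x and y directions).
#' @param ctc Centre-to-centre slit distance in mm.
#' @param thickness Collimator thickness in mm.
#' @param tilt_gradient Slit tilt per off-axis distance, degree/mm.
#' @param mode `"static-multislit"` (all slits open) or `"dynamic-aperture"`
#'   (a single slit scanned synchronously with the pencil-beam spots).
#' @return An object of class `collimator`.
#' @export
pmbrt_collimator <- function(n_slits = 15, slit_width = 0.4, slit_length = 45,
                             ctc = 4, thickness = 65, tilt_gradient = 0.025,
                             mode = c("static-multislit", "dynamic-aperture")) {
  mode <- match.arg(mode)
  if (n_slits < 1 || n_slits %% 2 == 0) {
    abort("`n_slits` must be odd so the central slit sits on the axis.",
          class = "minibeamr_config_error")
  }
  if (slit_width >= ctc) {
    abort("`slit_width` must be smaller than `ctc`.",
          class = "minibeamr_config_error")
  }
  if (thickness <= 0) {
    abort("`thickness` must be positive.", class = "minibeamr_config_error")
  }
  structure(
    list(n_slits = n_slits, slit_width = slit_width, slit_length = slit_length,
         ctc = ctc, thickness = thickness, tilt_gradient = tilt_gradient,
         mode = mode),
    class = "collimator"
  )
}

#' @export
print.collimator <- function(x, ...) {
  cat(sprintf("<collimator> %d slits %.1f x %.0f mm^2, ctc %.1f mm, %.0f mm thick, tilt %.3f deg/mm, %s\n",
              x$n_slits, x$slit_width, x$slit_length, x$ctc, x$thickness,
              x$tilt_gradient, x$mode))
  invisible(x)
}

# Signed tilt (radians) of a slit at off-axis distance x1 (mm): the tilt
# follows the beam divergence, pointing away from the axis.
slit_tilt_rad <- function(x1_mm, collimator = pmbrt_collimator()) {
  collimator$tilt_gradient * x1_mm * pi / 180
}

#' Slit positions and tilts
#'
#' @param collimator A [pmbrt_collimator()].
#' @return A tibble with one row per slit: `slit` (index, 0 on axis),
#'   `x1_mm` (off-axis distance `k * ctc`) and `tilt_rad` (signed, pointing
#'   away from the axis; 0 on axis).
#' @export
slit_positions <- function(collimator = pmbrt_collimator()) {
  k <- seq.int(-(collimator$n_slits - 1) / 2, (collimator$n_slits - 1) / 2)
  x1 <- k * collimator$ctc
  tibble(slit = k, x1_mm = x1, tilt_rad = slit_tilt_rad(x1, collimator))
}

#' Per-slit transmission weights of a pencil-beam spot
#'
#' In static-multislit mode a pencil beam with a Gaussian transverse profile
#' also irradiates slits adjacent to the one it is aligned with; the weight of
#' each slit is the integral of the spot Gaussian over the slit aperture. In
#' dynamic-aperture mode the spot irradiates only the single aperture aligned
#' with it (weight 1), all other weights are zero.
#'
#' @param spot_x Spot centre x coordinate in mm.
#' @param spot_sigma Spot Gaussian sigma in mm (`> 0`).
#' @inheritParams slit_positions
#' @return A tibble `slit`, `x1_mm`, `weight`.
#' @export
slit_transmission_weights <- function(spot_x, spot_sigma,
                                      collimator = pmbrt_collimator()) {
  if (spot_sigma <= 0) {
    abort("`spot_sigma` must be positive.", class = "minibeamr_domain_error")
  }
  slits <- slit_positions(collimator)
  if (collimator$mode == "dynamic-aperture") {
    aligned <- abs(slits$x1_mm - spot_x) < 1e-9
    slits$weight <- as.numeric(aligned)
  } else {
    a <- collimator$slit_width / 2
    slits$weight <- pnorm((slits$x1_mm + a - spot_x) / spot_sigma) -
      pnorm((slits$x1_mm - a - spot_x) / spot_sigma)
  }
  slits[, c("slit", "x1_mm", "weight")]
}

#' Pencil-beam-scanning spot grid
#'
#' Default grid: 31 x 17 spots, 3 mm vertical spacing, horizontal spacing
#' equal to the collimator ctc distance.
#'
#' @param n_x,n_y Number of spots in x (scan/bending) and y (slit length).
#' @param dx,dy Spot spacings in mm.
#' @param spot_sigma Transverse Gaussian sigma of a pencil beam at the
#'   collimator plane, mm.
#' @return An object of class `spot_grid`.
#' @export
spot_grid <- function(n_x = 31, n_y = 17, dx = 4, dy = 3, spot_sigma = 3) {
  if (n_x < 1 || n_y < 1 || dx <= 0 || dy <= 0 || spot_sigma <= 0) {
    abort("Spot grid dimensions and spacings must be positive.",
          class = "minibeamr_config_error")
  }
  structure(list(n_x = n_x, n_y = n_y, dx = dx, dy = dy,
                 spot_sigma = spot_sigma),
            class = "spot_grid")
}

spot_x_positions <- function(grid) {
  seq.int(-(grid$n_x - 1) / 2, (grid$n_x - 1) / 2) * grid$dx
}

SCENARIO_NAMES <- c("config1", "config2", "config2p", "config3", "config3p")

#' Beamline scenario presets
#'
#' The five configurations compared in the study:
#' * `config1` — reference: static multislit collimator, ctc 4 mm, no field.
#' * `config2` — static multislit, ctc 6 mm, 50 mm dipole after the collimator.
#' * `config2p` — as `config2` with a dynamic scanning aperture.
#' * `config3` — static multislit, ctc 6 mm, uniform field inside the phantom
#'   (MRI-guided-like).
#' * `config3p` — as `config3` with a dynamic scanning aperture.
#'
#' All share a 70 mm collimator-to-phantom air gap, a 10 x 10 x 30 cm^3 water
#' phantom and a 31 x 17 spot grid with dy = 3 mm and dx equal to the ctc.
#'
#' @param name One of `"config1"`, `"config2"`, `"config2p"`, `"config3"`,
#'   `"config3p"`.
#' @param spot_sigma Pencil-beam Gaussian sigma at the collimator plane (mm).
#' @param ... Collimator overrides passed to [pmbrt_collimator()]
#'   (e.g. `n_slits`, `tilt_gradient`) for reduced or degenerate scenarios.
#' @return An object of class `scenario`.
#' @export
make_scenario <- function(name, spot_sigma = 3, ...) {
  if (!is.character(name) || length(name) != 1 || !(name %in% SCENARIO_NAMES)) {
    abort(paste0("Unknown scenario name. Valid names: ",
                 paste(SCENARIO_NAMES, collapse = ", "), "."),
          class = "minibeamr_config_error")
  }
  ctc <- if (name == "config1") 4 else 6
  mode <- if (name %in% c("config2p", "config3p")) "dynamic-aperture" else "static-multislit"
  field_region <- switch(name,
    config1 = "none",
    config2 = , config2p = "dipole",
    config3 = , config3p = "phantom"
  )
  coll <- pmbrt_collimator(ctc = ctc, mode = mode, ...)
  structure(
    list(
      name = name,
      collimator = coll,
      spot_grid = spot_grid(dx = coll$ctc, spot_sigma = spot_sigma),
      air_gap = 70,
      dipole_thickness = if (field_region == "dipole") 50 else NA_real_,
      field_region = field_region,
      reference_ctc = 4,
      phantom_size = c(100, 100, 300),
      dose_voxels = c(0.1, 2, 1)
    ),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s: ctc %.1f mm, %s, field region: %s\n",
              x$name, x$collimator$ctc, x$collimator$mode, x$field_region))
  invisible(x)
}
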