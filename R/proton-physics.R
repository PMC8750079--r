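#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom dplyr mutate filter arrange select group_by summarise ungroup
#'   bind_rows left_join
#' @importFrom purrr map map_dbl pmap imap
#' @importFrom stats approx approxfun uniroot pnorm dnorm rnorm runif
#'   splinefun convolve coef lm
NULL

# Physical constants (MeV, mm, tesla, radians).
PROTON_MASS_MEV <- 938.272
MEV_PER_TESLA_M <- 299.792458 # p [MeV/c] = 299.792458 * B rho [T m]
WATER_X0_MM <- 360.8          # radiation length of water
E_MAX_MEV <- 230              # supported maximum kinetic energy

#' Relativistic proton momentum from kinetic energy
#'
#' @param energy_mev Kinetic energy in MeV (vectorised, `>= 0`).
#' @return Momentum in MeV/c, `sqrt(E (E + 2 m))` with the proton rest mass
#'   energy m = 938.272 MeV.
#' @examples
#' momentum_from_energy(100) # ~444.6 MeV/c
#' @export
momentum_from_energy <- function(energy_mev) {
  if (any(energy_mev < 0)) {
    abort("`energy_mev` must be non-negative.", class = "minibeamr_domain_error")
  }
  sqrt(energy_mev * (energy_mev + 2 * PROTON_MASS_MEV))
}

# v/c of a proton with kinetic energy E.
proton_beta <- function(energy_mev) {
  momentum_from_energy(energy_mev) / (energy_mev + PROTON_MASS_MEV)
}

#' Magnetic rigidity of a proton
#'
#' The rigidity B*rho = p/q links momentum to the Larmor radius
#' `r = rigidity / B` in a uniform field B.
#'
#' @param energy_mev Kinetic energy in MeV (vectorised, `> 0`).
#' @return Rigidity in T m.
#' @examples
#' magnetic_rigidity(100)        # ~1.483 T m
#' magnetic_rigidity(100) / 1    # Larmor radius in m for B = 1 T
#' @export
magnetic_rigidity <- function(energy_mev) {
  if (any(energy_mev <= 0)) {
    abort("`energy_mev` must be positive.", class = "minibeamr_domain_error")
  }
  momentum_from_energy(energy_mev) / MEV_PER_TESLA_M
}

#' Range-energy model for protons in water
#'
#' Either a Bragg-Kleeman power law `R = alpha * E^p` or a monotone
#' interpolation of the bundled CSDA range table. The two modes agree within
#' 2% over 70-230 MeV.
#'
#' @param mode `"power-law"` (default) or `"tabulated"`.
#' @param alpha Bragg-Kleeman coefficient in cm MeV^-p (default 0.0022).
#' @param p Bragg-Kleeman exponent (default 1.77).
#' @param table Optional data frame with columns `energy_mev`, `range_mm`
#'   overriding the bundled CSDA table.
#' @return An object of class `range_model`.
#' @export
range_model <- function(mode = c("power-law", "tabulated"),
                        alpha = 0.0022, p = 1.77, table = NULL) {
  mode <- match.arg(mode)
  if (alpha <= 0 || p <= 0) {
    abort("`alpha` and `p` must be positive.", class = "minibeamr_config_error")
  }
  model <- list(mode = mode, alpha_mm = alpha * 10, p = p)
  if (mode == "tabulated") {
    if (is.null(table)) table <- read_bundled_range_table()
    stopifnot(all(c("energy_mev", "range_mm") %in% names(table)))
    table <- dplyr::arrange(as_tibble(table), .data$energy_mev)
    if (any(diff(table$range_mm) <= 0)) {
      abort("Range table must be strictly increasing in energy.",
            class = "minibeamr_config_error")
    }
    # log-log monotone spline above the first tabulated point; power-law
    # continuation (matched at the first point) below it
    sp <- splinefun(log(table$energy_mev), log(table$range_mm), method = "hyman")
    e_min <- min(table$energy_mev)
    r_min <- min(table$range_mm)
    model$table <- table
    model$fwd <- function(e) {
      r <- numeric(length(e))
      hi <- e >= e_min
      r[hi] <- exp(sp(log(e[hi])))
      lo <- !hi & e > 0
      r[lo] <- r_min * (e[lo] / e_min)^p
      r
    }
  }
  structure(model, class = "range_model")
}

read_bundled_range_table <- function() {
  path <- system.file("extdata", "water_csda_range.csv", package = "minibeamr")
  if (path == "") path <- file.path("inst", "extdata", "water_csda_range.csv")
  as_tibble(utils::read.csv(path, comment.char = "#"))
}

#' @export
print.range_model <- function(x, ...) {
  cat("<range_model> mode:", x$mode,
      sprintf("(alpha = %.4g cm MeV^-p, p = %.3g)\n", x$alpha_mm / 10, x$p))
  invisible(x)
}

#' Proton CSDA range in water
#'
#' @param energy_mev Kinetic energy in MeV (vectorised, 0 to 230).
#' @param model A [range_model()].
#' @return Range in mm of water.
#' @examples
#' range_in_water(100) # ~77 mm
#' @export
range_in_water <- function(energy_mev, model = range_model()) {
  if (any(energy_mev < 0)) {
    abort("`energy_mev` must be non-negative.", class = "minibeamr_domain_error")
  }
  if (any(energy_mev > E_MAX_MEV)) {
    abort(sprintf("`energy_mev` above the supported maximum (%d MeV).", E_MAX_MEV),
          class = "minibeamr_domain_error")
  }
  if (model$mode == "power-law") {
    model$alpha_mm * energy_mev^model$p
  } else {
    model$fwd(energy_mev)
  }
}

# Dense inverse lookup E(R). Built once per model and memoised in the model's
# environment would complicate the value semantics; callers on hot paths use
# inverse_range_fun() directly.
inverse_range_fun <- function(model = range_model(), e_max = E_MAX_MEV) {
  if (model$mode == "power-law") {
    alpha <- model$alpha_mm
    p <- model$p
    function(r_mm) (pmax(r_mm, 0) / alpha)^(1 / p)
  } else {
    e_grid <- c(seq(0, 10, by = 0.02), seq(10.05, e_max, by = 0.05))
    r_grid <- range_in_water(e_grid, model)
    fn <- approxfun(r_grid, e_grid, rule = 2)
    function(r_mm) fn(pmax(r_mm, 0))
  }
}

#' Proton energy from residual range in water
#'
#' Exact inverse of [range_in_water()] in the model's active mode.
#'
#' @param residual_range_mm Residual range in mm (`>= 0`).
#' @inheritParams range_in_water
#' @return Kinetic energy in MeV.
#' @export
energy_from_residual_range <- function(residual_range_mm, model = range_model()) {
  if (any(residual_range_mm < 0)) {
    abort("`residual_range_mm` must be non-negative.",
          class = "minibeamr_domain_error")
  }
  r_max <- range_in_water(E_MAX_MEV, model)
  if (any(residual_range_mm > r_max + 1e-9)) {
    abort("`residual_range_mm` exceeds the range at the supported maximum energy.",
          class = "minibeamr_domain_error")
  }
  inverse_range_fun(model)(residual_range_mm)
}

#' Range straggling width
#'
#' Gaussian sigma of the range-straggling distribution, parameterised as
#' `coefficient * R^exponent` with R the CSDA range in mm (about 1% of the
#' range in water).
#'
#' @inheritParams range_in_water
#' @param coefficient,exponent Straggling parameterisation (defaults 0.012,
#'   0.935, lengths in mm).
#' @return Sigma in mm.
#' @export
range_straggling_sigma <- function(energy_mev, model = range_model(),
                                   coefficient = 0.012, exponent = 0.935) {
  if (any(energy_mev <= 0)) {
    abort("`energy_mev` must be positive.", class = "minibeamr_domain_error")
  }
  coefficient * range_in_water(energy_mev, model)^exponent
}

#' Highland multiple-Coulomb-scattering angle
#'
#' Highland's parameterisation of the projected scattering angle sigma for a
#' water step, `14.1/(p v) * sqrt(t/X0) * (1 + log10(t/X0)/9)` with `p v` in
#' MeV and X0 = 360.8 mm.
#'
#' @param energy_mev Kinetic energy in MeV (`> 0`).
#' @param step_mm Water thickness traversed in mm (`> 0`).
#' @param radiation_length_mm Radiation length, default water (360.8 mm).
#' @return Angular sigma in radians.
#' @export
highland_sigma_theta <- function(energy_mev, step_mm,
                                 radiation_length_mm = WATER_X0_MM) {
  if (any(energy_mev <= 0)) {
    abort("`energy_mev` must be positive.", class = "minibeamr_domain_error")
  }
  if (any(step_mm <= 0)) {
    abort("`step_mm` must be positive.", class = "minibeamr_domain_error")
  }
  pv <- momentum_from_energy(energy_mev) * proton_beta(energy_mev)
  t <- step_mm / radiation_length_mm
  14.1 / pv * sqrt(t) * (1 + log10(t) / 9)
}
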