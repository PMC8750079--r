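# x-z profile matrix averaged over the central y window
xz_profile_matrix <- function(dose, y_halfwidth = 5) {
  sel <- abs(dose$y_mm) <= y_halfwidth
  if (!any(sel)) sel <- which.min(abs(dose$y_mm))
  apply(dose$values[, sel, , drop = FALSE], c(1, 3), mean)
}

# indices of strict interior local maxima of a numeric vector
local_maxima_idx <- function(v) {
  n <- length(v)
  if (n < 3) return(integer())
  which(v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1
}

# First off-axis minibeam peak and the valley between it and the axis, for
# one transverse profile. Returns list(peak0, valley, valley_x, peak1_x).
slice_extrema <- function(x, p) {
  peak0 <- approx(x, p, 0, rule = 2)$y
  pos <- which(x > 0)
  xm <- local_maxima_idx(p[pos])
  if (length(xm) == 0) {
    # no off-axis peak (uniform or single-ridge profile): search the whole
    # positive half
    inter <- pos
  } else {
    first_peak <- pos[min(xm)]
    inter <- pos[x[pos] < x[first_peak]]
  }
  if (length(inter) == 0) {
    return(list(peak = peak0, valley = peak0, valley_x = NA_real_))
  }
  vi <- inter[which.min(p[inter])]
  list(peak = peak0, valley = p[vi], valley_x = x[vi])
}

#' Peak-to-valley dose ratio as a function of depth
#'
#' At each depth slice (averaged over a central y window) the peak is the
#' dose on the central minibeam axis (x = 0) and the valley is the minimum
#' dose strictly between the central and the first off-axis minibeam peak at
#' that depth (located per slice, because converging minibeams shift with
#' depth). A zero valley yields an infinite PVDR, flagged rather than raised.
#'
#' @param dose A `dose_grid` with a central minibeam at x = 0.
#' @param y_halfwidth Central y averaging half-window, mm.
#' @return A tibble `z_mm`, `peak_dose`, `valley_dose`, `valley_x_mm`,
#'   `pvdr`, `infinite`.
#' @export
pvdr_series <- function(dose, y_halfwidth = 5) {
  pm <- xz_profile_matrix(dose, y_halfwidth)
  rows <- purrr::map(seq_along(dose$z_mm), function(j) {
    e <- slice_extrema(dose$x_mm, pm[, j])
    tibble(z_mm = dose$z_mm[j], peak_dose = e$peak, valley_dose = e$valley,
           valley_x_mm = e$valley_x)
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(
      pvdr = dplyr::if_else(.data$valley_dose > 0,
                            .data$peak_dose / .data$valley_dose,
                            Inf),
      infinite = !(.data$valley_dose > 0))
}

#' Valley dose as a function of depth
#'
#' Valley locations as in [pvdr_series()]; returns the dose values.
#'
#' @inheritParams pvdr_series
#' @return A tibble `z_mm`, `valley_dose`, `valley_x_mm`.
#' @export
valley_series <- function(dose, y_halfwidth = 5) {
  pvdr_series(dose, y_halfwidth)[, c("z_mm", "valley_dose", "valley_x_mm")]
}

#' Maximum discrepancy between two profiles over the flat region
#'
#' The flat region is where a smoothed envelope of the reference profile —
#' linear interpolation through its per-period peak tops, because minibeam
#' profiles are oscillatory and a raw threshold would select only peak
#' cores — reaches at least `isodose_fraction` of its maximum. Returns
#' `max |test - ref| / ref * 100` over that region.
#'
#' @param profile_ref,profile_test Tibbles `x_mm`, `dose` on the same x grid.
#' @param isodose_fraction Envelope threshold (default 0.95).
#' @param normalize `"none"` (default: compare raw values) or `"mean"`
#'   (rescale the test profile to the reference mean over the flat region
#'   first; appropriate when the two deliveries are only defined up to a
#'   relative dose scale).
#' @return Maximum relative discrepancy in percent.
#' @export
flat_region_discrepancy <- function(profile_ref, profile_test,
                                    isodose_fraction = 0.95,
                                    normalize = c("none", "mean")) {
  normalize <- match.arg(normalize)
  if (nrow(profile_ref) != nrow(profile_test) ||
      max(abs(profile_ref$x_mm - profile_test$x_mm)) > 1e-9) {
    abort("Profiles must share the same x grid.",
          class = "minibeamr_config_error")
  }
  x <- profile_ref$x_mm
  ref <- profile_ref$dose
  test <- profile_test$dose
  pk <- local_maxima_idx(ref)
  env <- ref
  if (length(pk) >= 2) {
    # peak-top interpolation between the outermost detected peaks; outside
    # that span the profile roll-off itself is the envelope
    span <- seq(min(pk), max(pk))
    env[span] <- approx(x[pk], ref[pk], x[span])$y
  }
  region <- which(env >= isodose_fraction * max(env))
  if (length(region) == 0 || all(ref[region] <= 0)) {
    abort("Empty flat region at this isodose fraction.",
          class = "minibeamr_domain_error")
  }
  if (normalize == "mean") {
    test <- test * mean(ref[region]) / mean(test[region])
  }
  max(abs(test[region] - ref[region]) / ref[region]) * 100
}

#' Bragg-peak depth retraction in a magnetic field
#'
#' The curved trajectory of a minibeam deflected in-phantom is longer than
#' its depth extent, so the Bragg peak pulls upstream: the retraction is
#' `R(E)` minus the depth reached when the accumulated path length equals
#' `R(E)`.
#'
#' @param energy_mev Kinetic energy in MeV.
#' @param field_t Uniform in-phantom field in tesla (signed).
#' @param entry_angle Entry angle in radians (e.g. the slit tilt).
#' @param model A [range_model()].
#' @param step RK4 step in mm.
#' @return Retraction in mm (0 for a straight beam at normal incidence).
#' @export
bragg_retraction <- function(energy_mev, field_t, entry_angle = 0,
                             model = range_model(), step = 0.1) {
  tr <- integrate_trajectory(0, entry_angle, field_t, energy_mev,
                             stop = "at-range", step = step, model = model,
                             x_bounds = c(-Inf, Inf))
  range_in_water(energy_mev, model) - attr(tr, "end_z")
}

#' Export PVDR / valley metrics to CSV
#'
#' @param series A [pvdr_series()] tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(series, path) {
  readr::write_csv(
    dplyr::select(series, z_mm = "z_mm", pvdr = "pvdr",
                  valley_dose = "valley_dose", peak_dose = "peak_dose"),
    path)
  invisible(path)
}
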