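#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_raster geom_rect
#'   geom_point labs scale_fill_viridis_c theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a dose grid as an x-z dose map
#'
#' Central-y-window dose map in the bending plane.
#'
#' @param object A `dose_grid`.
#' @param y_halfwidth Central y averaging half-window, mm.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dose_grid <- function(object, y_halfwidth = 5, ...) {
  pm <- xz_profile_matrix(object, y_halfwidth)
  df <- tidyr::expand_grid(z_mm = object$z_mm, x_mm = object$x_mm) |>
    dplyr::mutate(dose = as.vector(pm))
  ggplot(df, aes(x = .data$z_mm, y = .data$x_mm, fill = .data$dose)) +
    geom_raster() +
    scale_fill_viridis_c() +
    labs(x = "depth z (mm)", y = "x (mm)", fill = "dose (rel.)",
         title = object$scenario_name %||% "dose grid") +
    theme_minimal()
}

#' Plot an optimized field table
#'
#' Field strength against slit off-axis distance, one line per energy.
#'
#' @param object A `field_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.field_table <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$slit_offset_mm, y = .data$field_T,
             colour = factor(.data$energy_MeV))) +
    geom_line() + geom_point() +
    labs(x = "slit off-axis distance (mm)", y = "field (T)",
         colour = "energy (MeV)") +
    theme_minimal()
}

#' Plot an SOBP plan
#'
#' Weighted layer contributions and the combined peak-dose curve, with the
#' flattening window shaded.
#'
#' @param object A `sobp_plan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sobp_plan <- function(object, ...) {
  lib <- object$library
  layers <- purrr::imap(seq_along(lib$energies), function(i, ...) {
    tibble(z_mm = lib$z_mm, dose = lib$peak[, i] * object$weights[i],
           curve = sprintf("%g MeV", lib$energies[i]))
  }) |> dplyr::bind_rows()
  total <- dplyr::mutate(combined_peak_dose(object$weights, lib),
                         curve = "combined")
  ggplot(dplyr::bind_rows(layers, total),
         aes(x = .data$z_mm, y = .data$dose, colour = .data$curve)) +
    geom_rect(aes(xmin = object$window[1], xmax = object$window[2],
                  ymin = -Inf, ymax = Inf),
              inherit.aes = FALSE, fill = "grey92") +
    geom_line() +
    labs(x = "depth z (mm)", y = "peak dose (rel.)", colour = NULL) +
    theme_minimal()
}

#' Plot PVDR or valley dose against depth
#'
#' @param series Named list of [pvdr_series()] tibbles (names become curve
#'   labels), or a single tibble.
#' @param what `"pvdr"` or `"valley_dose"`.
#' @return A ggplot.
#' @export
plot_depth_series <- function(series, what = c("pvdr", "valley_dose")) {
  what <- match.arg(what)
  if (is.data.frame(series)) series <- list(series = series)
  df <- purrr::imap(series, function(s, nm) {
    dplyr::mutate(s, configuration = nm)
  }) |> dplyr::bind_rows()
  ggplot(dplyr::filter(df, is.finite(.data[[what]])),
         aes(x = .data$z_mm, y = .data[[what]],
             colour = .data$configuration)) +
    geom_line() +
    labs(x = "depth z (mm)", y = what) +
    theme_minimal()
}
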