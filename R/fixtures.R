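#' Synthetic inputs with known analytic properties
#'
#' Deterministic fixture generators for testing and demonstration:
#' * `"cosine-grid"` — a dose grid `D(x) = offset + amplitude * cos(2 pi x /
#'   ctc)`, uniform in y and z, whose PVDR is exactly
#'   `(offset + amplitude) / (offset - amplitude)`;
#' * `"toy-library-2"` — two overlapping triangular depth curves with a
#'   grid-search-verifiable optimal weight ratio;
#' * `"toy-library-5"` — five raised-cosine lobes forming an exact partition
#'   of unity, divided by planted weights `w*` so that weighting by `w*`
#'   yields a perfectly flat plateau;
#' * `"single-slit-scenario"` — a degenerate one-slit, zero-tilt scenario
#'   producing a single dose ridge.
#'
#' @param kind Fixture kind, see Details.
#' @param seed RNG seed (fixtures are deterministic; the seed is recorded
#'   for provenance).
#' @param ... Kind-specific overrides: `offset`, `amplitude`, `ctc`
#'   (cosine grid); `planted_weights` (5-layer library).
#' @return The fixture object (a `dose_grid`, `dose_library` or `scenario`).
#' @export
make_fixtures <- function(kind = c("cosine-grid", "toy-library-2",
                                   "toy-library-5", "single-slit-scenario"),
                          seed = 1, ...) {
  kind <- match.arg(kind)
  opts <- list(...)
  switch(kind,
    "cosine-grid" = {
      offset <- opts$offset %||% 2
      amplitude <- opts$amplitude %||% 1
      ctc <- opts$ctc %||% 6
      x <- seq(-3 * ctc, 3 * ctc, by = ctc / 60) # centres include 0 and ctc
      y <- seq(-20, 20, by = 10)
      z <- seq(1, 299, by = 10)
      prof <- offset + amplitude * cos(2 * pi * x / ctc)
      vals <- array(rep(prof, times = length(y) * length(z)),
                    c(length(x), length(y), length(z)))
      dose_grid(vals, x, y, z)
    },
    "toy-library-2" = {
      z <- seq(140, 200, by = 0.25)
      tri <- function(center, width) pmax(1 - abs(z - center) / width, 0)
      dose_library(z, energies = c(150, 158),
                   peak = cbind(tri(160, 18), tri(172, 18)))
    },
    "toy-library-5" = {
      w_star <- opts$planted_weights %||% c(0.2, 0.3, 0.45, 0.7, 1)
      stopifnot(length(w_star) == 5, all(w_star > 0))
      z <- seq(140, 205, by = 0.25)
      d <- 7.5
      centers <- 157.5 + d * (0:4)
      # raised-cosine lobes: adjacent lobes sum to 1 exactly between centres
      lobe <- function(c0) {
        u <- (z - c0) / d
        ifelse(abs(u) < 1, cos(pi * u / 2)^2, 0)
      }
      peak <- vapply(seq_along(centers),
                     function(i) lobe(centers[i]) / w_star[i],
                     numeric(length(z)))
      lib <- dose_library(z, energies = c(150, 154, 158, 162, 166),
                          peak = peak)
      attr(lib, "planted_weights") <- w_star
      attr(lib, "flat_window") <- c(centers[1], centers[5])
      lib
    },
    "single-slit-scenario" = {
      make_scenario("config1", n_slits = 1, tilt_gradient = 0)
    })
}
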