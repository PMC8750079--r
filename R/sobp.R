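#' Per-energy depth-dose library for SOBP optimization
#'
#' Central-minibeam peak-dose depth curves, one per energy layer, on a common
#' depth grid. Two sources:
#' * `"bragg"` (default): the analytical broadened Bragg curves of
#'   [bragg_depth_dose()] (a pristine depth-dose library);
#' * `"engine"`: central-axis peak-dose (and valley) curves extracted from
#'   [compute_dose()] grids of a scenario, which include the lateral
#'   convergence and scattering of the full minibeam pattern.
#'
#' @param energies Energy layers in MeV (default the five 150-166 MeV layers,
#'   4 MeV steps).
#' @param z_mm Common depth grid in mm.
#' @param source `"bragg"` or `"engine"`.
#' @param scenario,field_table Needed for `source = "engine"`.
#' @param model A [range_model()].
#' @param energy_spread Relative beam energy spread dE/E.
#' @param sigma0 Collimator-exit beam sigma (engine source), mm.
#' @param grid Engine grid mode.
#' @param peak_align Optional depth calibration `c(z_first, z_last)` in mm: a
#'   linear map of the depth axis placing the first and last layers' Bragg
#'   peak maxima at the stated depths, the way a commissioned machine's
#'   measured peak depths calibrate a range model. `NULL` (default) leaves
#'   the model's native peak positions.
#' @return A `dose_library`: list with `z_mm`, `energies`, `peak` (matrix
#'   depth x energy) and `valley` (engine source only).
#' @export
sobp_dose_library <- function(energies = c(150, 154, 158, 162, 166),
                              z_mm = seq(100, 220, by = 0.5),
                              source = c("bragg", "engine"),
                              scenario = NULL, field_table = NULL,
                              model = range_model(), energy_spread = 0.01,
                              sigma0 = 0.2, grid = "coarse",
                              peak_align = NULL) {
  source <- match.arg(source)
  stopifnot(length(energies) >= 1)
  if (source == "bragg") {
    peak <- vapply(energies, function(e) {
      bragg_depth_dose(e, z_mm, model, energy_spread = energy_spread)
    }, numeric(length(z_mm)))
    valley <- NULL
  } else {
    if (is.null(scenario)) {
      abort("`scenario` is required for source = \"engine\".",
            class = "minibeamr_config_error")
    }
    curves <- purrr::map(energies, function(e) {
      d <- compute_dose(scenario, e, field_table, grid = grid,
                        sigma0 = sigma0, energy_spread = energy_spread,
                        model = model)
      s <- pvdr_series(d)
      list(peak = approx(s$z_mm, s$peak_dose, z_mm, rule = 2)$y,
           valley = approx(s$z_mm, s$valley_dose, z_mm, rule = 2)$y)
    })
    peak <- vapply(curves, `[[`, numeric(length(z_mm)), "peak")
    valley <- vapply(curves, `[[`, numeric(length(z_mm)), "valley")
  }
  if (!is.null(peak_align)) {
    stopifnot(length(peak_align) == 2, diff(peak_align) > 0)
    ord <- order(energies)
    p_lo <- z_mm[which.max(peak[, ord[1]])]
    p_hi <- z_mm[which.max(peak[, ord[length(ord)]])]
    if (p_hi <= p_lo) {
      abort("Cannot align peaks: degenerate peak span.",
            class = "minibeamr_config_error")
    }
    # sample the old curves at the depths that map onto the new peak span
    z_old <- p_lo + (z_mm - peak_align[1]) * (p_hi - p_lo) / diff(peak_align)
    peak <- apply(peak, 2, function(cl) approx(z_mm, cl, z_old, rule = 2)$y)
    if (!is.null(valley)) {
      valley <- apply(valley, 2, function(cl) approx(z_mm, cl, z_old, rule = 2)$y)
    }
  }
  structure(list(z_mm = z_mm, energies = as.numeric(energies), peak = peak,
                 valley = valley, source = source),
            class = "dose_library")
}

#' Construct a dose library from explicit curves
#'
#' @param z_mm Depth grid.
#' @param energies Energy labels, MeV.
#' @param peak Matrix (depth x energy) of non-negative peak-dose curves.
#' @return A `dose_library`.
#' @export
dose_library <- function(z_mm, energies, peak) {
  peak <- as.matrix(peak)
  stopifnot(nrow(peak) == length(z_mm), ncol(peak) == length(energies),
            all(peak >= 0))
  structure(list(z_mm = z_mm, energies = as.numeric(energies), peak = peak,
                 valley = NULL, source = "explicit"),
            class = "dose_library")
}

#' @export
print.dose_library <- function(x, ...) {
  cat(sprintf("<dose_library> %d layers (%s MeV), %d depths, source: %s\n",
              length(x$energies), paste(x$energies, collapse = ", "),
              length(x$z_mm), x$source))
  invisible(x)
}

#' Weighted SOBP peak-dose depth curve
#'
#' `Dp(z) = sum_i w_i Dp_i(z)`: linear in the layer weights.
#'
#' @param weights Layer weights (one per library energy, `>= 0`).
#' @param library A [sobp_dose_library()].
#' @return A tibble `z_mm`, `dose`.
#' @export
combined_peak_dose <- function(weights, library) {
  if (length(weights) != length(library$energies)) {
    abort("`weights` must have one entry per energy layer.",
          class = "minibeamr_config_error")
  }
  tibble(z_mm = library$z_mm, dose = as.numeric(library$peak %*% weights))
}

#' SOBP flatness fitness
#'
#' The maximum dose error of the combined peak-dose curve within the SOBP
#' window: `f = max(Dp) - min(Dp)` over the window (absolute form), or the
#' same divided by the window mean and expressed in percent (relative form).
#'
#' @inheritParams combined_peak_dose
#' @param window Depth window `c(z_min, z_max)` in mm (default 157-187 mm).
#' @param type `"absolute"` or `"relative"` (percent of the window mean).
#' @return A scalar fitness (lower is flatter).
#' @export
sobp_fitness <- function(weights, library, window = c(157, 187),
                         type = c("absolute", "relative")) {
  type <- match.arg(type)
  sel <- library$z_mm >= window[1] & library$z_mm <= window[2]
  if (!any(sel)) {
    abort("Empty SOBP window on this depth grid.",
          class = "minibeamr_config_error")
  }
  dp <- as.numeric(library$peak[sel, , drop = FALSE] %*% weights)
  f <- max(dp) - min(dp)
  if (type == "relative") f <- f / mean(dp) * 100
  f
}

#' Genetic-algorithm configuration
#'
#' Hyperparameters of the SOBP weight optimizer. The seed is mandatory: runs
#' are reproducible by contract.
#'
#' @param population_size Population size (`>= 2`).
#' @param generations Number of generations.
#' @param crossover_rate Per-individual arithmetic crossover probability.
#' @param mutation_rate Per-gene Gaussian mutation probability.
#' @param mutation_scale Mutation sigma on log-weights.
#' @param elite_count Elites copied unchanged each generation.
#' @param tournament_size Tournament selection size.
#' @param seed RNG seed (required).
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 60, generations = 300,
                      crossover_rate = 0.9, mutation_rate = 0.2,
                      mutation_scale = 0.1, elite_count = 2,
                      tournament_size = 3, seed) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is mandatory for reproducible optimization.",
          class = "minibeamr_config_error")
  }
  if (population_size < 2) {
    abort("`population_size` must be at least 2.",
          class = "minibeamr_config_error")
  }
  rates <- c(crossover_rate, mutation_rate)
  if (any(rates < 0 | rates > 1)) {
    abort("Rates must lie in [0, 1].", class = "minibeamr_config_error")
  }
  list(population_size = population_size, generations = generations,
       crossover_rate = crossover_rate, mutation_rate = mutation_rate,
       mutation_scale = mutation_scale, elite_count = elite_count,
       tournament_size = tournament_size, seed = as.integer(seed))
}

#' Optimize SOBP layer weights with a genetic algorithm
#'
#' Minimizes the flatness fitness of [sobp_fitness()] over the layer
#' weights. The highest-energy (distal) layer weight is fixed to 1 — the
#' absolute fitness is invariant only up to the overall dose scale, and
#' reported weights are conventionally normalized to the last layer — and
#' the remaining weights are evolved on a log scale with tournament
#' selection, elitism, arithmetic crossover and Gaussian mutation. Fixed
#' seed implies identical output.
#'
#' @inheritParams sobp_fitness
#' @param control A [ga_config()].
#' @return A `sobp_plan`: energies, normalized weights (last = 1), window,
#'   absolute and relative fitness, best-fitness history, and the library.
#' @export
ga_optimize <- function(library, window = c(157, 187),
                        control = ga_config(seed = 1)) {
  n_e <- length(library$energies)
  if (n_e < 2) {
    abort("The library needs at least 2 energy layers.",
          class = "minibeamr_config_error")
  }
  sel <- library$z_mm >= window[1] & library$z_mm <= window[2]
  if (!any(sel)) {
    abort("Empty SOBP window on this depth grid.",
          class = "minibeamr_config_error")
  }
  d_win <- library$peak[sel, , drop = FALSE]
  n_g <- n_e - 1 # free genes: log-weights of all but the distal layer
  evaluate <- function(pop) {
    w <- cbind(exp(pop), 1)
    m <- d_win %*% t(w)
    apply(m, 2, function(cl) max(cl) - min(cl))
  }
  withr::with_seed(control$seed, {
    pop <- matrix(runif(control$population_size * n_g, log(0.01), log(2)),
                  control$population_size, n_g)
    fit <- evaluate(pop)
    best_hist <- numeric(control$generations)
    for (gen in seq_len(control$generations)) {
      ord <- order(fit)
      n_elite <- min(control$elite_count, control$population_size)
      children <- matrix(0, control$population_size, n_g)
      children[seq_len(n_elite), ] <- pop[ord[seq_len(n_elite)], , drop = FALSE]
      pick <- function() {
        cand <- sample.int(control$population_size, control$tournament_size,
                           replace = TRUE)
        cand[which.min(fit[cand])]
      }
      for (i in seq_len(control$population_size - n_elite) + n_elite) {
        p1 <- pop[pick(), ]
        if (runif(1) < control$crossover_rate) {
          p2 <- pop[pick(), ]
          u <- runif(n_g)
          child <- u * p1 + (1 - u) * p2
        } else {
          child <- p1
        }
        mut <- runif(n_g) < control$mutation_rate
        child[mut] <- child[mut] + rnorm(sum(mut), 0, control$mutation_scale)
        children[i, ] <- child
      }
      pop <- children
      fit <- evaluate(pop)
      best_hist[gen] <- min(fit)
    }
    best <- pop[which.min(fit), ]
    weights <- c(exp(best), 1)
    # best-so-far is monotone by elitism; enforce against ties in storage
    best_hist <- cummin(best_hist)
    new_sobp_plan(library, weights, window, best_hist, control)
  })
}

new_sobp_plan <- function(library, weights, window, history, control) {
  structure(
    list(energies = library$energies, weights = weights, window = window,
         fitness = sobp_fitness(weights, library, window, "absolute"),
         max_dose_error_pct = sobp_fitness(weights, library, window, "relative"),
         history = tibble(generation = seq_along(history),
                          best_fitness = history),
         library = library, control = control),
    class = "sobp_plan")
}

#' @export
print.sobp_plan <- function(x, ...) {
  cat(sprintf("<sobp_plan> %d layers, window %g-%g mm, max dose error %.2f%%\n",
              length(x$energies), x$window[1], x$window[2],
              x$max_dose_error_pct))
  print(generics::tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an SOBP plan into a weights table
#'
#' @param x A `sobp_plan`.
#' @param ... Unused.
#' @return A tibble `energy_MeV`, `weight` (normalized to the distal layer).
#' @export
tidy.sobp_plan <- function(x, ...) {
  tibble(energy_MeV = x$energies, weight = x$weights)
}

#' One-row summary of an SOBP plan
#'
#' @inheritParams tidy.sobp_plan
#' @return A tibble with the window, fitness and GA bookkeeping.
#' @export
glance.sobp_plan <- function(x, ...) {
  tibble(n_layers = length(x$energies),
         window_min_mm = x$window[1], window_max_mm = x$window[2],
         fitness = x$fitness, max_dose_error_pct = x$max_dose_error_pct,
         generations = x$control$generations,
         population_size = x$control$population_size,
         seed = x$control$seed)
}
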