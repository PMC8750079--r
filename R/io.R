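#' Read / write a field table as CSV
#'
#' Columns: `configuration`, `slit_offset_mm`, `energy_MeV`, `field_T`.
#'
#' @param field_table A `field_table` tibble.
#' @param path CSV path.
#' @return `path` (write) or a `field_table` (read).
#' @export
write_field_table <- function(field_table, path) {
  readr::write_csv(as_tibble(field_table), path)
  invisible(path)
}

#' @rdname write_field_table
#' @export
read_field_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          configuration = readr::col_character(),
                          slit_offset_mm = readr::col_double(),
                          energy_MeV = readr::col_double(),
                          field_T = readr::col_double()))
  new_field_table(df)
}

#' Write / read a dose grid as MetaImage (.mhd + .raw)
#'
#' Plain-text MetaImage header with voxel spacing and grid origin (the
#' coordinate of the first voxel centre), raw little-endian doubles in x, y,
#' z order. Round-trips bit-exactly.
#'
#' @param dose A `dose_grid`.
#' @param path Path of the `.mhd` header; the `.raw` file sits next to it.
#' @return `path` (write) or a `dose_grid` (read).
#' @export
write_dose_grid <- function(dose, path) {
  if (!grepl("\\.mhd$", path)) path <- paste0(path, ".mhd")
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  dims <- dim(dose$values)
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", dims[1], dims[2], dims[3]),
    sprintf("ElementSpacing = %.17g %.17g %.17g",
            dose$voxel_mm[1], dose$voxel_mm[2], dose$voxel_mm[3]),
    sprintf("Offset = %.17g %.17g %.17g",
            dose$x_mm[1], dose$y_mm[1], dose$z_mm[1]),
    "ElementType = MET_DOUBLE",
    sprintf("ElementDataFile = %s", raw_name)
  )
  writeLines(header, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(as.vector(dose$values), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  val <- function(k) kv[[match(k, keys)]][2]
  dims <- as.integer(strsplit(val("DimSize"), " ")[[1]])
  spacing <- as.numeric(strsplit(val("ElementSpacing"), " ")[[1]])
  offset <- as.numeric(strsplit(val("Offset"), " ")[[1]])
  raw_path <- file.path(dirname(path), val("ElementDataFile"))
  con <- file(raw_path, "rb")
  on.exit(close(con))
  values <- readBin(con, "double", n = prod(dims), size = 8,
                    endian = "little")
  dose_grid(array(values, dims),
            x = offset[1] + (seq_len(dims[1]) - 1) * spacing[1],
            y = offset[2] + (seq_len(dims[2]) - 1) * spacing[2],
            z = offset[3] + (seq_len(dims[3]) - 1) * spacing[3])
}

#' Write an SOBP plan as JSON and CSV
#'
#' @param plan A `sobp_plan`.
#' @param path Output path stem; writes `<stem>.json` and `<stem>.csv`
#'   (`energy_MeV`, `weight_normalized`).
#' @return The JSON path, invisibly.
#' @export
write_sobp_plan <- function(plan, path) {
  stem <- sub("\\.(json|csv)$", "", path)
  readr::write_csv(
    dplyr::rename(generics::tidy(plan), weight_normalized = "weight"),
    paste0(stem, ".csv"))
  jsonlite::write_json(
    list(energies_MeV = plan$energies, weights = plan$weights,
         window_mm = plan$window, fitness = plan$fitness,
         max_dose_error_pct = plan$max_dose_error_pct,
         seed = plan$control$seed),
    paste0(stem, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(paste0(stem, ".json"))
}

RUN_CONFIG_KEYS <- c("scenario", "energies", "sobp", "grid", "output_dir",
                     "seed", "log_level", "range_mode", "drift", "sigma0",
                     "energy_spread")
SOBP_CONFIG_KEYS <- c("energies", "window", "population_size", "generations",
                      "crossover_rate", "mutation_rate", "mutation_scale",
                      "elite_count", "tournament_size")

#' Read and validate a run configuration
#'
#' YAML run configuration for the command-line entry points. Recognized
#' keys: `scenario` (name), `energies`, `sobp` (block with `energies`,
#' `window` and GA hyperparameters), `grid` (`coarse`/`full`),
#' `output_dir`, `seed`, `log_level`, `range_mode`, `drift`, `sigma0`,
#' `energy_spread`. Unknown keys are rejected before any computation.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config A raw configuration list.
#' @export
validate_run_config <- function(config) {
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
  if (length(unknown) > 0) {
    abort(paste0("Unknown configuration keys: ",
                 paste(unknown, collapse = ", "), "."),
          class = "minibeamr_config_error")
  }
  if (is.null(config$scenario)) {
    abort("`scenario` is required.", class = "minibeamr_config_error")
  }
  if (!config$scenario %in% SCENARIO_NAMES) {
    abort(paste0("Unknown scenario name. Valid names: ",
                 paste(SCENARIO_NAMES, collapse = ", "), "."),
          class = "minibeamr_config_error")
  }
  if (!is.null(config$sobp)) {
    unknown <- setdiff(names(config$sobp), SOBP_CONFIG_KEYS)
    if (length(unknown) > 0) {
      abort(paste0("Unknown sobp keys: ", paste(unknown, collapse = ", "), "."),
            class = "minibeamr_config_error")
    }
  }
  config$grid <- config$grid %||% "coarse"
  if (!config$grid %in% c("coarse", "full")) {
    abort("`grid` must be \"coarse\" or \"full\".",
          class = "minibeamr_config_error")
  }
  config$range_mode <- config$range_mode %||% "power-law"
  config$output_dir <- config$output_dir %||% "."
  config$seed <- as.integer(config$seed %||% 1L)
  config$log_level <- config$log_level %||% "info"
  config$sigma0 <- config$sigma0 %||% 0.2
  config$energy_spread <- config$energy_spread %||% 0.01
  config$drift <- config$drift %||% "air+range"
  structure(config, class = "run_config")
}
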