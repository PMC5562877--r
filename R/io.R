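#' Write an annual cube to plain-text storage
#'
#' Serializes a cube as a long CSV (`row,col,year,value`) plus a JSON
#' sidecar (`<path>.json`) carrying the grid definition, the cube kind and
#' the nodata sentinel. Missing values are written as the sentinel (-9999
#' for numeric kinds, 255 for categorical/binary). Integer-kind values
#' round-trip bit-exactly; numeric values are written at full precision
#' (15 significant digits).
#'
#' @param cube An [annual_cube()].
#' @param path Output CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  nodata <- if (cube$kind %in% c("categorical", "binary")) 255 else -9999
  df <- as_tibble.annual_cube(cube)
  df$value[is.na(df$value)] <- nodata
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(
    grid = unclass(cube$grid), kind = cube$kind, nodata = nodata,
    years = grid_years(cube$grid)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an annual cube written by [write_cube()]
#'
#' @param path CSV path; the `<path>.json` sidecar must be present.
#' @return An [annual_cube()] with sentinels restored to NA.
#' @export
read_cube <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("missing grid sidecar: ", sidecar, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  grid <- do.call(grid_spec, meta$grid)
  df <- utils::read.csv(path)
  need <- c("row", "col", "year", "value")
  if (!all(need %in% names(df))) {
    stop("cube CSV must have columns row, col, year, value", call. = FALSE)
  }
  df$value[df$value == meta$nodata] <- NA_real_
  cube_from_tibble(tibble::as_tibble(df), grid, kind = meta$kind)
}

#' Assemble and validate a run configuration
#'
#' A single bag of settings for an end-to-end run. Unknown keys are
#' rejected by name, so a typo in a config never silently falls back to a
#' default. The configuration round-trips losslessly through
#' [write_run_config()] / [read_run_config()].
#'
#' @param grid A [grid_spec()] (or the list of its fields).
#' @param mix Event-kind proportions for [make_truth()].
#' @param detector [detector_params()] (or the list of its fields).
#' @param windows List with integer year vectors `t1` and `t2` for the
#'   period-comparison recipes.
#' @param land_area_km2 Reference land area for coverage percentages.
#' @param seed Integer seed for every stochastic stage.
#' @param noise List with `sigma_nbr`, `flip_prob_lc`, `sigma_vcf_pct`.
#' @param ... Must be empty; any further named argument is rejected.
#' @return A `run_config` list.
#' @export
run_config <- function(grid = grid_spec(40, 40),
                       mix = c(stable_forest = 0.40, stable_nonforest = 0.25,
                               abrupt_loss = 0.15, gradual_gain = 0.12,
                               loss_then_recovery = 0.08),
                       detector = detector_params(),
                       windows = list(t1 = 2001:2003, t2 = 2010:2012),
                       land_area_km2 = NULL, seed = 1L,
                       noise = list(sigma_nbr = 0.02, flip_prob_lc = 0.05,
                                    sigma_vcf_pct = 5), ...) {
  extras <- list(...)
  if (length(extras) > 0) {
    stop("unknown configuration key(s): ",
         paste(names(extras), collapse = ", "), call. = FALSE)
  }
  if (!inherits(grid, "grid_spec")) grid <- do.call(grid_spec, grid)
  if (!inherits(detector, "detector_params")) {
    detector <- do.call(detector_params, detector)
  }
  structure(list(grid = grid, mix = mix, detector = detector,
                 windows = windows, land_area_km2 = land_area_km2,
                 seed = as.integer(seed), noise = noise),
            class = "run_config")
}

#' Write a run configuration as JSON
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  out <- list(grid = unclass(config$grid), mix = as.list(config$mix),
              detector = unclass(config$detector),
              windows = config$windows,
              land_area_km2 = config$land_area_km2, seed = config$seed,
              noise = config$noise)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a run configuration from JSON
#' @param path JSON path written by [write_run_config()].
#' @return A [run_config()]; unknown keys in the file are rejected.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("grid", "mix", "detector", "windows", "land_area_km2", "seed",
             "noise")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  run_config(
    grid = raw$grid, mix = unlist(raw$mix),
    detector = raw$detector,
    windows = lapply(raw$windows, as.integer),
    land_area_km2 = raw$land_area_km2,
    seed = raw$seed, noise = raw$noise
  )
}
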