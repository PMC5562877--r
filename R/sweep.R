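#' Sweep one detector parameter
#'
#' Runs the trajectory detector once per value of a single parameter, all
#' other parameters held at `params`, and reports national loss and gain as
#' areas and coverage percentages. Rows are computed independently in the
#' order of `values` — each row is reproducible by a direct
#' [detect_changes()] + accounting call at that value.
#'
#' @param cube Index [annual_cube()].
#' @param param_name One of `"forest_threshold"`, `"change_threshold"`,
#'   `"mask_cover_threshold"`. The last re-derives the forest mask from
#'   `cover_map` at each threshold (percent).
#' @param values Numeric values to sweep.
#' @param params Baseline [detector_params()].
#' @param mask Forest-domain mask (logical matrix) used for the two
#'   threshold parameters; ignored for `"mask_cover_threshold"`.
#' @param cover_map Percent tree-cover matrix, required for
#'   `"mask_cover_threshold"`.
#' @param land_area_km2 Denominator for the coverage percentages (defaults
#'   to the grid's own total area, so percentages refer to the scene).
#' @return Tibble `(value, loss_km2, gain_km2, loss_pct, gain_pct)`.
#' @export
sweep_detector_params <- function(cube,
                                  param_name = c("change_threshold",
                                                 "forest_threshold",
                                                 "mask_cover_threshold"),
                                  values, params = detector_params(),
                                  mask = NULL, cover_map = NULL,
                                  land_area_km2 = NULL) {
  param_name <- match.arg(param_name)
  grid <- cube$grid
  if (is.null(land_area_km2)) {
    land_area_km2 <- grid$rows * grid$cols * pixel_area_km2(grid)
  }
  if (param_name == "mask_cover_threshold" && is.null(cover_map)) {
    stop("`cover_map` is required to sweep the mask threshold",
         call. = FALSE)
  }
  purrr::map(values, function(v) {
    p <- params
    m <- mask
    if (param_name == "mask_cover_threshold") {
      m <- cover_map >= v
    } else {
      p[[param_name]] <- v
    }
    cm <- detect_changes(cube, params = p, mask = m)
    a <- binary_change_area(cm, grid)
    tibble::tibble(value = v, loss_km2 = a$loss_km2, gain_km2 = a$gain_km2,
                   loss_pct = coverage_percent(a$loss_km2, land_area_km2),
                   gain_pct = coverage_percent(a$gain_km2, land_area_km2))
  }) |>
    dplyr::bind_rows()
}

#' Effect of the forest-mask cover threshold
#'
#' Re-derives the detector's forest mask as `cover >= threshold` for each
#' threshold, runs the detector, and reports masked land area plus loss and
#' gain areas. Raising the threshold shrinks the forest domain, which can
#' only reduce the loss area (loss labels are confined to the mask).
#'
#' @param cube Index [annual_cube()].
#' @param cover_map Percent tree-cover matrix matching the cube grid.
#' @param thresholds Percent thresholds to test.
#' @param params [detector_params()] held fixed.
#' @return Tibble `(threshold, mask_area_km2, loss_km2, gain_km2)`.
#' @export
mask_threshold_effect <- function(cube, cover_map, thresholds,
                                  params = detector_params()) {
  grid <- cube$grid
  px <- pixel_area_km2(grid)
  purrr::map(thresholds, function(th) {
    m <- cover_map >= th
    cm <- detect_changes(cube, params = params, mask = m)
    a <- binary_change_area(cm, grid)
    tibble::tibble(threshold = th, mask_area_km2 = sum(m) * px,
                   loss_km2 = a$loss_km2, gain_km2 = a$gain_km2)
  }) |>
    dplyr::bind_rows()
}

#' Baseline forest area under alternative forest definitions
#'
#' For each (product, definition) pair, the forest area at the start of the
#' period: the areal sum of forest pixels for categorical maps (class-set
#' definition) and binarized fractional maps (cover-threshold definition),
#' or the areal sum of fractional cover itself (fractional definition,
#' sub-pixel accounting of all non-zero cover).
#'
#' @param products Named list of baseline maps: integer class matrices for
#'   class-set definitions, percent-cover matrices otherwise.
#' @param definitions Named list of [forest_definition()]s; names pair rows
#'   (`product` x `definition` combinations are supplied explicitly as a
#'   tibble via `combos`, or by crossing when `combos` is NULL and kinds
#'   are compatible).
#' @param combos Optional tibble `(product, definition)` naming which pairs
#'   to evaluate; by default every definition is applied to every product
#'   whose data kind matches (class matrices with class sets, percent maps
#'   with thresholds/fractional).
#' @param grid The shared [grid_spec()].
#' @param land_area_km2 Denominator for the coverage column (defaults to
#'   the grid total).
#' @return Tibble `(product, definition, forest_area_km2, coverage_pct)`.
#' @export
definition_experiment <- function(products, definitions, grid,
                                  combos = NULL, land_area_km2 = NULL) {
  px <- pixel_area_km2(grid)
  if (is.null(land_area_km2)) {
    land_area_km2 <- grid$rows * grid$cols * px
  }
  if (is.null(combos)) {
    combos <- tidyr::expand_grid(product = names(products),
                                 definition = names(definitions))
    keep <- purrr::map2_lgl(combos$product, combos$definition, function(p, d) {
      def <- definitions[[d]]
      is_class <- is.integer(products[[p]]) ||
        isTRUE(attr(products[[p]], "categorical"))
      (def$kind == "class_set") == is_class
    })
    combos <- combos[keep, ]
  }
  purrr::pmap(combos, function(product, definition) {
    map <- products[[product]]
    def <- definitions[[definition]]
    area <- switch(def$kind,
      class_set = sum(map %in% def$class_codes, na.rm = TRUE) * px,
      cover_threshold = sum(binarize_cover(map, def), na.rm = TRUE) * px,
      fractional = sum(map / 100, na.rm = TRUE) * px
    )
    tibble::tibble(product = product, definition = definition,
                   forest_area_km2 = area,
                   coverage_pct = coverage_percent(area, land_area_km2))
  }) |>
    dplyr::bind_rows()
}
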