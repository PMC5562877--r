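#' Binary change-area accounting
#'
#' On an equal-area grid the area of a binary change class is simply the
#' label count times the pixel area.
#'
#' @param map A `change_map`.
#' @param grid The [grid_spec()] the map lives on (defaults to the map's
#'   own grid).
#' @return One-row tibble `(loss_km2, gain_km2)`.
#' @examples
#' g <- grid_spec(10, 10, pixel_size_m = 500)
#' lab <- matrix(0L, 10, 10); lab[1:4] <- 1L
#' binary_change_area(forestflux:::new_change_map(lab, grid = g), g)
#' @export
binary_change_area <- function(map, grid = map$grid) {
  px <- pixel_area_km2(grid)
  tibble::tibble(
    loss_km2 = sum(map$label == 1L, na.rm = TRUE) * px,
    gain_km2 = sum(map$label == 2L, na.rm = TRUE) * px
  )
}

#' Sub-pixel fractional change-area accounting
#'
#' Each pixel contributes its changed cover fraction times the pixel area:
#' `loss = sum(|delta| / 100 * pixel_area)` over negative deltas, gain
#' analogously over positive ones. This keeps the quantitative meaning of
#' fractional products intact instead of whole-pixel counting.
#'
#' @param map A `fraction_change` (signed percent deltas).
#' @param grid The [grid_spec()] (defaults to the map's own grid).
#' @return One-row tibble `(loss_km2, gain_km2)`.
#' @export
fractional_change_area <- function(map, grid = map$grid) {
  px <- pixel_area_km2(grid)
  d <- map$delta
  tibble::tibble(
    loss_km2 = sum(pmax(0, -d) / 100, na.rm = TRUE) * px,
    gain_km2 = sum(pmax(0, d) / 100, na.rm = TRUE) * px
  )
}

#' Convert an area to coverage percent of a land area
#'
#' `100 * area / land_area`. The default land area is 9.6 million km^2
#' (China's conventional national land area); it is a parameter because
#' every headline "coverage" number depends on the denominator chosen.
#'
#' @param area_km2 Area (km^2); may be negative for net change.
#' @param land_area_km2 Reference land area (km^2), > 0.
#' @return Coverage percent (same sign as `area_km2`).
#' @examples
#' coverage_percent(2076500 - 1749100)   # net national change, percent
#' @export
coverage_percent <- function(area_km2, land_area_km2 = 9.6e6) {
  if (any(land_area_km2 <= 0, na.rm = TRUE)) {
    stop("`land_area_km2` must be positive", call. = FALSE)
  }
  100 * area_km2 / land_area_km2
}

#' Aggregate a change map to provincial statistics
#'
#' Sums loss and gain areas within each province of a full-coverage
#' partition, using binary accounting for label maps and sub-pixel
#' fractional accounting for fractional maps. Pixels without a province ID
#' are reported in an explicit `unassigned` row (ID `NA`), never dropped,
#' so provincial rows always sum to the national totals.
#'
#' @param map A `change_map` or `fraction_change`.
#' @param provinces Integer matrix of province IDs matching the map shape
#'   (NA = unassigned).
#' @param land_areas Tibble `(province_id, land_area_km2)` as returned by
#'   [render_provinces()]; may carry extra columns (e.g. forest area),
#'   which are preserved.
#' @param grid The [grid_spec()] (defaults to the map's own grid).
#' @return A province table: one row per province (plus `unassigned` when
#'   needed) with `loss_km2`, `gain_km2`, `net_km2 = gain - loss`, and
#'   `loss_pct`, `gain_pct`, `net_pct` as percent of provincial land area.
#' @export
provincial_aggregate <- function(map, provinces, land_areas,
                                 grid = map$grid) {
  px <- pixel_area_km2(grid)
  if (inherits(map, "change_map")) {
    if (!all(dim(provinces) == dim(map$label))) {
      stop("province raster does not match the change map", call. = FALSE)
    }
    df <- tibble::tibble(
      province_id = as.vector(provinces),
      loss = as.numeric(as.vector(map$label) == 1L) * px,
      gain = as.numeric(as.vector(map$label) == 2L) * px
    )
  } else if (inherits(map, "fraction_change")) {
    if (!all(dim(provinces) == dim(map$delta))) {
      stop("province raster does not match the change map", call. = FALSE)
    }
    d <- as.vector(map$delta)
    df <- tibble::tibble(
      province_id = as.vector(provinces),
      loss = pmax(0, -d) / 100 * px,
      gain = pmax(0, d) / 100 * px
    )
  } else {
    stop("`map` must be a change_map or fraction_change", call. = FALSE)
  }
  sums <- df |>
    dplyr::group_by(.data$province_id) |>
    dplyr::summarise(loss_km2 = sum(.data$loss, na.rm = TRUE),
                     gain_km2 = sum(.data$gain, na.rm = TRUE),
                     .groups = "drop")
  out <- dplyr::full_join(land_areas, sums, by = "province_id") |>
    dplyr::mutate(
      loss_km2 = dplyr::coalesce(.data$loss_km2, 0),
      gain_km2 = dplyr::coalesce(.data$gain_km2, 0),
      net_km2 = .data$gain_km2 - .data$loss_km2,
      loss_pct = coverage_percent(.data$loss_km2, .data$land_area_km2),
      gain_pct = coverage_percent(.data$gain_km2, .data$land_area_km2),
      net_pct = coverage_percent(.data$net_km2, .data$land_area_km2)
    ) |>
    dplyr::arrange(is.na(.data$province_id), .data$province_id)
  out
}
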