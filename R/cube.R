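#' Annual raster cube
#'
#' A stack of single-band annual rasters on one grid: a numeric index in
#' \[-1, 1\] (NBR-like), percent cover in \[0, 100\] (VCF-like), categorical
#' codes, or binary flags. Missing observations are `NA` internally; nodata
#' sentinels only appear on disk (see [write_cube()]).
#'
#' @param values Numeric array `rows x cols x n_years` (a matrix is accepted
#'   for a single-year cube).
#' @param grid The [grid_spec()] the values live on; its year span must match
#'   the third dimension.
#' @param kind One of `"index"`, `"percent"`, `"categorical"`, `"binary"`,
#'   `"fraction"`; recorded for method dispatch and plotting, not enforced on
#'   the values.
#'
#' @return An `annual_cube` object.
#' @export
annual_cube <- function(values, grid, kind = "index") {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  if (length(dim(values)) != 3L) {
    stop("`values` must be a rows x cols x years array", call. = FALSE)
  }
  n_years <- length(grid_years(grid))
  if (!all(dim(values)[1:2] == c(grid$rows, grid$cols)) ||
      dim(values)[3] != n_years) {
    stop("`values` dimensions do not match the grid", call. = FALSE)
  }
  kind <- match.arg(kind, c("index", "percent", "categorical", "binary",
                            "fraction"))
  structure(
    list(values = values, grid = grid, kind = kind),
    class = "annual_cube"
  )
}

#' @export
print.annual_cube <- function(x, ...) {
  cat(sprintf(
    "<annual_cube:%s> %d x %d x %d years (%d-%d), %d NA\n",
    x$kind, x$grid$rows, x$grid$cols, dim(x$values)[3],
    x$grid$year_start, x$grid$year_end, sum(is.na(x$values))
  ))
  invisible(x)
}

#' Extract one year's layer from a cube
#' @param cube An [annual_cube()].
#' @param year Calendar year present in the cube's span.
#' @return A `rows x cols` matrix.
#' @export
cube_layer <- function(cube, year) {
  yrs <- grid_years(cube$grid)
  i <- match(year, yrs)
  if (is.na(i)) stop("year not covered by the cube", call. = FALSE)
  cube$values[, , i, drop = TRUE]
}

#' Tidy a cube into a long tibble
#'
#' @param x An [annual_cube()].
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `year`, `value`.
#' @method as_tibble annual_cube
#' @export
as_tibble.annual_cube <- function(x, ...) {
  yrs <- grid_years(x$grid)
  tidyr::expand_grid(year = yrs, col = seq_len(x$grid$cols),
                     row = seq_len(x$grid$rows)) |>
    dplyr::mutate(value = as.vector(x$values)) |>
    dplyr::select("row", "col", "year", "value") |>
    dplyr::arrange(.data$row, .data$col, .data$year)
}

#' Rebuild a cube from a long tibble
#'
#' Inverse of [as_tibble.annual_cube()]; rows may arrive in any order.
#'
#' @param df Tibble with `row`, `col`, `year`, `value`.
#' @param grid Target [grid_spec()].
#' @param kind Cube kind, as in [annual_cube()].
#' @return An [annual_cube()].
#' @export
cube_from_tibble <- function(df, grid, kind = "index") {
  yrs <- grid_years(grid)
  vals <- array(NA_real_, dim = c(grid$rows, grid$cols, length(yrs)))
  yi <- match(df$year, yrs)
  if (anyNA(yi)) stop("tibble contains years outside the grid span",
                      call. = FALSE)
  vals[cbind(df$row, df$col, yi)] <- df$value
  annual_cube(vals, grid, kind = kind)
}
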