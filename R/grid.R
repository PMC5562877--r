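#' Define an equal-area raster grid
#'
#' All layers in a scene share one grid. The grid is an abstract equal-area
#' partition (pixel rows by columns at a fixed pixel size), so area accounting
#' reduces to pixel counting: `pixel_area_km2 = (pixel_size_m / 1000)^2`.
#' Raster indexing is row-major from the top-left corner, 1-based, with a
#' pixel-centre coordinate convention.
#'
#' @param rows,cols Number of pixel rows and columns (>= 1).
#' @param pixel_size_m Pixel edge length in metres (> 0).
#' @param origin_x,origin_y Projected coordinates (m) of the top-left corner.
#' @param year_start,year_end First and last calendar year of the annual
#'   series carried on this grid (`year_end >= year_start`).
#'
#' @return A `grid_spec` object.
#' @examples
#' g <- grid_spec(10, 10, pixel_size_m = 500)
#' pixel_area_km2(g)
#' @export
grid_spec <- function(rows, cols, pixel_size_m = 500,
                      origin_x = 0, origin_y = 0,
                      year_start = 2000, year_end = 2013) {
  rows <- as.integer(rows)
  cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 1L || cols < 1L) {
    stop("grid must have at least one row and one column", call. = FALSE)
  }
  if (!is.numeric(pixel_size_m) || pixel_size_m <= 0) {
    stop("`pixel_size_m` must be positive", call. = FALSE)
  }
  if (year_end < year_start) {
    stop("`year_end` must not precede `year_start`", call. = FALSE)
  }
  structure(
    list(
      rows = rows, cols = cols,
      pixel_size_m = as.numeric(pixel_size_m),
      origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
      year_start = as.integer(year_start), year_end = as.integer(year_end)
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d pixels @ %g m (%g km2/pixel), years %d-%d\n",
    x$rows, x$cols, x$pixel_size_m, pixel_area_km2(x), x$year_start, x$year_end
  ))
  invisible(x)
}

#' Pixel area of a grid in square kilometres
#' @param grid A [grid_spec()].
#' @return Scalar area of one pixel in km^2.
#' @export
pixel_area_km2 <- function(grid) {
  (grid$pixel_size_m / 1000)^2
}

#' Years covered by a grid
#' @param grid A [grid_spec()].
#' @return Integer vector `year_start:year_end`.
#' @export
grid_years <- function(grid) {
  seq.int(grid$year_start, grid$year_end)
}

#' Refine a grid by an integer factor
#'
#' Splits every pixel into `factor x factor` children covering the same
#' extent (used to emulate finer-resolution sensors sharing a footprint).
#'
#' @param grid A [grid_spec()].
#' @param factor Integer refinement factor (>= 1).
#' @return A finer `grid_spec`.
#' @export
refine_grid <- function(grid, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) {
    stop("`factor` must be an integer >= 1", call. = FALSE)
  }
  grid_spec(
    rows = grid$rows * factor, cols = grid$cols * factor,
    pixel_size_m = grid$pixel_size_m / factor,
    origin_x = grid$origin_x, origin_y = grid$origin_y,
    year_start = grid$year_start, year_end = grid$year_end
  )
}

#' Coarsen a grid by an integer factor
#' @param grid A [grid_spec()]; dimensions must be divisible by `factor`.
#' @param factor Integer aggregation factor (>= 1).
#' @return A coarser `grid_spec`.
#' @export
coarsen_grid <- function(grid, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) {
    stop("`factor` must be an integer >= 1", call. = FALSE)
  }
  if (grid$rows %% factor != 0L || grid$cols %% factor != 0L) {
    stop("grid dimensions must be divisible by `factor`", call. = FALSE)
  }
  grid_spec(
    rows = grid$rows %/% factor, cols = grid$cols %/% factor,
    pixel_size_m = grid$pixel_size_m * factor,
    origin_x = grid$origin_x, origin_y = grid$origin_y,
    year_start = grid$year_start, year_end = grid$year_end
  )
}

same_grid <- function(a, b) {
  a$rows == b$rows && a$cols == b$cols &&
    isTRUE(all.equal(a$pixel_size_m, b$pixel_size_m)) &&
    a$year_start == b$year_start && a$year_end == b$year_end
}

stopifnot_same_grid <- function(a, b, what = "inputs") {
  if (!same_grid(a, b)) {
    stop(sprintf("grid mismatch between %s", what), call. = FALSE)
  }
  invisible(TRUE)
}
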