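#' Render a spectral-index cube from a truth scene
#'
#' Maps fractional cover affinely onto an NBR-like index,
#' `index = level_bare + (level_forest - level_bare) * cover`, adds i.i.d.
#' Gaussian noise per pixel-year and clips to \[-1, 1\]. The affine model is
#' deliberately simple: the index responds linearly to cover, which is all
#' the trajectory detector assumes.
#'
#' @param scene A [make_truth()] scene.
#' @param level_forest Index value of full canopy (default 0.60).
#' @param level_bare Index value of bare ground (default 0.05); must be
#'   below `level_forest`.
#' @param sigma Standard deviation of the additive index noise (>= 0).
#' @param seed Integer seed for the noise draw.
#' @return An [annual_cube()] of kind `"index"`.
#' @export
render_nbr <- function(scene, level_forest = 0.60, level_bare = 0.05,
                       sigma = 0.02, seed = 1L) {
  if (level_forest <= level_bare) {
    stop("`level_forest` must exceed `level_bare`", call. = FALSE)
  }
  if (sigma < 0) stop("`sigma` must be non-negative", call. = FALSE)
  cover <- true_cover(scene)$values
  vals <- level_bare + (level_forest - level_bare) * cover
  if (sigma > 0) {
    vals <- vals + withr::with_seed(
      as.integer(seed), stats::rnorm(length(vals), 0, sigma))
  }
  vals <- pmin(1, pmax(-1, vals))
  annual_cube(array(vals, dim = dim(cover)), scene$grid, kind = "index")
}

#' Render an annual categorical land-cover series
#'
#' Thresholds true cover into a forest/non-forest code per pixel-year, then
#' flips each label independently with probability `flip_prob`, emulating
#' the spurious interannual class flicker of yearly classification products.
#'
#' @param scene A [make_truth()] scene.
#' @param cover_to_class_threshold Cover fraction at or above which the pixel
#'   is classified forest (default 0.6, the canopy-cover floor of the IGBP
#'   forest classes).
#' @param flip_prob Per-pixel-year label flip probability in \[0, 1).
#' @param forest_code,nonforest_code Integer class codes emitted (defaults:
#'   IGBP 1 = evergreen needleleaf forest, 12 = cropland).
#' @param seed Integer seed for the flips.
#' @return An [annual_cube()] of kind `"categorical"`.
#' @export
render_lc <- function(scene, cover_to_class_threshold = 0.6, flip_prob = 0,
                      forest_code = 1L, nonforest_code = 12L, seed = 1L) {
  if (cover_to_class_threshold <= 0 || cover_to_class_threshold >= 1) {
    stop("`cover_to_class_threshold` must lie in (0, 1)", call. = FALSE)
  }
  if (flip_prob < 0 || flip_prob >= 1) {
    stop("`flip_prob` must lie in [0, 1)", call. = FALSE)
  }
  cover <- true_cover(scene)$values
  forest <- cover >= cover_to_class_threshold
  if (flip_prob > 0) {
    flips <- withr::with_seed(
      as.integer(seed),
      stats::runif(length(forest)) < flip_prob
    )
    forest <- xor(forest, array(flips, dim = dim(forest)))
  }
  vals <- ifelse(forest, as.numeric(forest_code), as.numeric(nonforest_code))
  annual_cube(array(vals, dim = dim(cover)), scene$grid, kind = "categorical")
}

#' Render a fractional tree-cover series on a finer grid
#'
#' Replicates each truth pixel's cover to `refine_factor^2` children (the
#' children of one footprint share the parent trajectory), converts to
#' percent, adds Gaussian noise and clips to \[0, 100\].
#'
#' @param scene A [make_truth()] scene.
#' @param refine_factor Integer grid refinement per axis (default 2,
#'   emulating a 250 m product under a 500 m truth grid).
#' @param sigma_pct Noise standard deviation in percent cover (>= 0).
#' @param seed Integer seed for the noise draw.
#' @return An [annual_cube()] of kind `"percent"` on the refined grid.
#' @export
render_vcf <- function(scene, refine_factor = 2L, sigma_pct = 5, seed = 1L) {
  refine_factor <- as.integer(refine_factor)
  if (is.na(refine_factor) || refine_factor < 1L) {
    stop("`refine_factor` must be an integer >= 1", call. = FALSE)
  }
  if (sigma_pct < 0) stop("`sigma_pct` must be non-negative", call. = FALSE)
  cover <- true_cover(scene)$values
  fine_grid <- refine_grid(scene$grid, refine_factor)
  fine <- replicate_to_children(cover, refine_factor)
  vals <- 100 * fine
  if (sigma_pct > 0) {
    vals <- vals + withr::with_seed(
      as.integer(seed), stats::rnorm(length(vals), 0, sigma_pct))
  }
  vals <- pmin(100, pmax(0, vals))
  annual_cube(array(vals, dim = dim(fine)), fine_grid, kind = "percent")
}

#' Render fine-resolution annual loss, aggregated gain, and baseline cover
#'
#' Emulates a Landsat-style change product: per-year binary loss layers (a
#' fine pixel is flagged in the year its parent's cover first drops below
#' `forest_threshold`), one gain layer aggregated over the whole span (the
#' parent ends at or above the threshold having started below it), and a
#' baseline percent-cover layer for the first year.
#'
#' @param scene A [make_truth()] scene.
#' @param refine_factor Integer grid refinement per axis (default 16,
#'   a 30 m-class product under a 500 m truth grid).
#' @param forest_threshold Cover fraction defining forest for the loss/gain
#'   rule (default 0.5).
#' @return A list with elements `loss` (an [annual_cube()] of kind
#'   `"binary"`, one layer per year), `gain` (binary matrix), `baseline`
#'   (percent matrix, first year) and `grid` (the fine [grid_spec()]).
#' @export
render_gfc <- function(scene, refine_factor = 16L, forest_threshold = 0.5) {
  refine_factor <- as.integer(refine_factor)
  if (is.na(refine_factor) || refine_factor < 1L) {
    stop("`refine_factor` must be an integer >= 1", call. = FALSE)
  }
  cover <- true_cover(scene)$values
  yrs <- grid_years(scene$grid)
  forest <- cover >= forest_threshold
  n_years <- length(yrs)
  loss <- array(0, dim = dim(cover))
  # loss in the first year the pixel leaves the forest state for good or ill:
  # forest in the previous year, non-forest this year
  for (t in 2:n_years) {
    loss[, , t] <- as.numeric(forest[, , t - 1] & !forest[, , t])
  }
  gain <- (!forest[, , 1]) & forest[, , n_years]
  fine_grid <- refine_grid(scene$grid, refine_factor)
  loss_fine <- replicate_to_children(loss, refine_factor)
  list(
    loss = annual_cube(loss_fine, fine_grid, kind = "binary"),
    gain = replicate_to_children(
      matrix(as.numeric(gain), scene$grid$rows), refine_factor),
    baseline = replicate_to_children(
      100 * cover[, , 1, drop = TRUE], refine_factor),
    grid = fine_grid
  )
}

#' Partition a grid into rectangular provinces
#'
#' Splits the grid into `k_rows x k_cols` contiguous blocks of near-equal
#' size (remainders spread over the leading blocks), standing in for an
#' administrative partition on which provincial statistics are aggregated.
#'
#' @param grid A [grid_spec()].
#' @param k_rows,k_cols Number of province blocks per axis.
#' @return A list with `raster` (integer matrix of province IDs, numbered
#'   row-major from the top-left block) and `table` (tibble of
#'   `province_id`, `land_area_km2`).
#' @export
render_provinces <- function(grid, k_rows = 2L, k_cols = 2L) {
  k_rows <- as.integer(k_rows); k_cols <- as.integer(k_cols)
  if (k_rows < 1L || k_cols < 1L || k_rows > grid$rows || k_cols > grid$cols) {
    stop("province blocks must fit the grid", call. = FALSE)
  }
  row_block <- block_index(grid$rows, k_rows)
  col_block <- block_index(grid$cols, k_cols)
  raster <- outer(row_block, col_block,
                  function(r, c) (r - 1L) * k_cols + c)
  tab <- tibble::tibble(province_id = seq_len(k_rows * k_cols)) |>
    dplyr::mutate(land_area_km2 = as.numeric(
      tabulate(raster, nbins = k_rows * k_cols)) * pixel_area_km2(grid))
  list(raster = raster, table = tab)
}

block_index <- function(n, k) {
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(k), times = sizes)
}

# replicate each parent cell to factor x factor children (matrix or 3-d array)
replicate_to_children <- function(x, factor) {
  if (factor == 1L) return(x)
  if (is.matrix(x)) {
    x[rep(seq_len(nrow(x)), each = factor),
      rep(seq_len(ncol(x)), each = factor), drop = FALSE]
  } else {
    x[rep(seq_len(dim(x)[1]), each = factor),
      rep(seq_len(dim(x)[2]), each = factor), , drop = FALSE]
  }
}
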