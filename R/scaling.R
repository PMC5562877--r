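#' Block-average aggregation
#'
#' Each coarse cell is the mean of its `factor x factor` children, skipping
#' missing children; a coarse cell is NA only when every child is NA. On a
#' complete map the global mean is preserved exactly (linearity).
#'
#' @param fine Numeric matrix whose dimensions are divisible by `factor`.
#' @param factor Integer aggregation factor.
#' @return Coarse numeric matrix.
#' @export
aggregate_average <- function(fine, factor) {
  block_apply(fine, factor, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
}

#' Aggregate a fine binary map to coarse percent-of-change
#'
#' Each coarse cell is `100 * flagged children / total children`, turning a
#' fine binary change map into a sub-pixel fractional change map whose
#' fractional area accounting equals binary accounting of the fine map
#' exactly.
#'
#' @param fine Binary (0/1 or logical) matrix, dims divisible by `factor`.
#' @param factor Integer aggregation factor.
#' @return Coarse percent matrix in \[0, 100\].
#' @export
aggregate_fraction <- function(fine, factor) {
  storage.mode(fine) <- "double"
  block_apply(fine, factor, function(v) 100 * mean(v, na.rm = TRUE))
}

block_apply <- function(fine, factor, f) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("`factor` must be >= 1", call. = FALSE)
  if (factor == 1L) {
    return(matrix(apply(array(fine, c(1, length(fine))), 2, f),
                  nrow(fine), ncol(fine)))
  }
  nr <- nrow(fine); nc <- ncol(fine)
  if (nr %% factor != 0L || nc %% factor != 0L) {
    stop("map dimensions must be divisible by `factor`", call. = FALSE)
  }
  cr <- nr %/% factor; cc <- nc %/% factor
  out <- matrix(NA_real_, cr, cc)
  for (i in seq_len(cr)) {
    rows <- ((i - 1L) * factor + 1L):(i * factor)
    for (j in seq_len(cc)) {
      cols <- ((j - 1L) * factor + 1L):(j * factor)
      out[i, j] <- f(as.vector(fine[rows, cols]))
    }
  }
  out
}

#' Resample a map to a coarser grid by an integer factor
#'
#' Block-aligned analogues of the five standard raster resampling kernels:
#' `"nearest"` samples the fine pixel containing each coarse-cell centre;
#' `"average"` is the block mean (identical to [aggregate_average()]);
#' `"mode"` is the block majority (ties to the smallest value); `"bilinear"`
#' and `"cubic"` are separable interpolations evaluated at coarse-cell
#' centres from fine-cell centres (cubic uses the Catmull-Rom kernel,
#' a = -0.5, with results clipped to the input range). Interpolating kernels
#' are meaningless on class codes, so `bilinear`, `average` and `cubic` are
#' rejected when `categorical = TRUE`.
#'
#' @param map Numeric matrix; dimensions must be divisible by `factor`.
#' @param factor Integer coarsening factor (>= 1); 1 returns the input.
#' @param method One of `"nearest"`, `"bilinear"`, `"average"`, `"mode"`,
#'   `"cubic"`.
#' @param categorical Is the map class-coded? Guards against interpolating
#'   kernels.
#' @return Coarse matrix (`dim(map) / factor`).
#' @export
resample <- function(map, factor,
                     method = c("nearest", "bilinear", "average", "mode",
                                "cubic"),
                     categorical = FALSE) {
  method <- match.arg(method)
  factor <- as.integer(factor)
  if (categorical && method %in% c("bilinear", "average", "cubic")) {
    stop(sprintf("method '%s' is not suitable for categorical data; %s",
                 method, "use 'nearest' or 'mode'"), call. = FALSE)
  }
  if (factor == 1L) return(map)
  if (nrow(map) %% factor != 0L || ncol(map) %% factor != 0L) {
    stop("map dimensions must be divisible by `factor`", call. = FALSE)
  }
  switch(method,
    average = aggregate_average(map, factor),
    mode = block_apply(map, factor, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) return(NA_real_)
      counts <- table(v)
      as.numeric(min(as.numeric(names(counts)[counts == max(counts)])))
    }),
    nearest = {
      idx_r <- nearest_index(nrow(map) %/% factor, factor)
      idx_c <- nearest_index(ncol(map) %/% factor, factor)
      map[idx_r, idx_c, drop = FALSE]
    },
    bilinear = separable_interp(map, factor, kernel = "linear"),
    cubic = {
      out <- separable_interp(map, factor, kernel = "catmull_rom")
      rng <- range(map, na.rm = TRUE)
      pmin(pmax(out, rng[1]), rng[2])
    }
  )
}

# fine pixel containing each coarse-cell centre (pixel-centre convention)
nearest_index <- function(n_coarse, factor) {
  ceiling((seq_len(n_coarse) - 0.5) * factor)
}

# separable interpolation at coarse-cell centres from fine-cell centres
separable_interp <- function(map, factor, kernel) {
  W_r <- interp_weights(nrow(map), nrow(map) %/% factor, factor, kernel)
  W_c <- interp_weights(ncol(map), ncol(map) %/% factor, factor, kernel)
  W_r %*% map %*% t(W_c)
}

# n_coarse x n_fine weight matrix; sample positions use pixel centres,
# indices clamped at the edges (border replication)
interp_weights <- function(n_fine, n_coarse, factor, kernel) {
  W <- matrix(0, n_coarse, n_fine)
  for (i in seq_len(n_coarse)) {
    p <- (i - 0.5) * factor            # coarse centre, fine-pixel units
    u <- p + 0.5                       # fine centre k sits at coordinate k
    k <- floor(u)
    frac <- u - k
    if (kernel == "linear") {
      taps <- c(k, k + 1)
      w <- c(1 - frac, frac)
    } else {                           # Catmull-Rom, a = -0.5
      taps <- c(k - 1, k, k + 1, k + 2)
      w <- catmull_rom_weights(frac)
    }
    taps <- pmin(n_fine, pmax(1, taps))
    for (t in seq_along(taps)) W[i, taps[t]] <- W[i, taps[t]] + w[t]
  }
  W
}

catmull_rom_weights <- function(s) {
  a <- -0.5
  w <- numeric(4)
  x <- c(1 + s, s, 1 - s, 2 - s)       # |distance| of the four taps
  for (t in 1:4) {
    d <- x[t]
    w[t] <- if (d <= 1) {
      (a + 2) * d^3 - (a + 3) * d^2 + 1
    } else {
      a * d^3 - 5 * a * d^2 + 8 * a * d - 4 * a
    }
  }
  w
}

#' Run the resampling sensitivity experiment
#'
#' Compares forest-change areas after coarsening under each resampling
#' method against the original-resolution reference, under one of the two
#' orderings actually used in practice: `"change_then_scale"` resamples an
#' existing change map (how products that ship change layers are scaled);
#' `"scale_then_change"` resamples the two period maps first and re-extracts
#' change from the coarse maps (how resolution would affect products whose
#' change is derived from classified or fractional maps).
#'
#' @param x For `"change_then_scale"`: a `change_map` or `fraction_change`.
#'   For `"scale_then_change"`: a list with elements `t1` and `t2` (two
#'   period matrices — class codes for the categorical recipe, percent cover
#'   for the fractional recipe).
#' @param strategy `"change_then_scale"` or `"scale_then_change"`.
#' @param factor Integer coarsening factor.
#' @param grid The [grid_spec()] of the input (fine) maps.
#' @param methods Resampling methods to compare; methods unsuitable for the
#'   data kind are dropped.
#' @param recipe For `"scale_then_change"`: `"categorical"` or
#'   `"fractional"`.
#' @param definition Class-set [forest_definition()] for the categorical
#'   recipe.
#' @return Tibble `(method, loss_km2, gain_km2)` with one leading
#'   `"original"` row holding the fine-resolution reference areas.
#' @export
run_scaling_experiment <- function(x,
                                   strategy = c("change_then_scale",
                                                "scale_then_change"),
                                   factor, grid,
                                   methods = c("nearest", "bilinear",
                                               "average", "mode", "cubic"),
                                   recipe = c("fractional", "categorical"),
                                   definition =
                                     forest_definition("class_set")) {
  strategy <- match.arg(strategy)
  recipe <- match.arg(recipe)
  coarse_grid <- coarsen_grid(grid, factor)
  px_fine <- pixel_area_km2(grid)
  px_coarse <- pixel_area_km2(coarse_grid)

  if (strategy == "change_then_scale") {
    if (inherits(x, "change_map")) {
      b_loss <- matrix(as.numeric(x$label == 1L), nrow(x$label))
      b_gain <- matrix(as.numeric(x$label == 2L), nrow(x$label))
      ref <- binary_change_area(x, grid)
    } else if (inherits(x, "fraction_change")) {
      b_loss <- pmax(-x$delta, 0) / 100
      b_gain <- pmax(x$delta, 0) / 100
      ref <- fractional_change_area(x, grid)
    } else {
      stop("`x` must be a change_map or fraction_change", call. = FALSE)
    }
    rows <- purrr::map(methods, function(m) {
      rl <- resample(b_loss, factor, method = m)
      rg <- resample(b_gain, factor, method = m)
      tibble::tibble(method = m,
                     loss_km2 = sum(rl, na.rm = TRUE) * px_coarse,
                     gain_km2 = sum(rg, na.rm = TRUE) * px_coarse)
    })
  } else {
    if (!is.list(x) || is.null(x$t1) || is.null(x$t2)) {
      stop("`x` must be a list with period maps `t1` and `t2`",
           call. = FALSE)
    }
    if (recipe == "categorical") {
      methods <- intersect(methods, c("nearest", "mode"))
      ref <- binary_change_area(
        categorical_change(x$t1, x$t2, definition, grid), grid)
      rows <- purrr::map(methods, function(m) {
        cm <- categorical_change(
          resample(x$t1, factor, method = m, categorical = TRUE),
          resample(x$t2, factor, method = m, categorical = TRUE),
          definition, coarse_grid)
        binary_change_area(cm, coarse_grid) |>
          dplyr::mutate(method = m, .before = 1)
      })
    } else {
      ref <- fractional_change_area(fractional_change(x$t1, x$t2, grid),
                                    grid)
      rows <- purrr::map(methods, function(m) {
        fc <- fractional_change(resample(x$t1, factor, method = m),
                                resample(x$t2, factor, method = m),
                                coarse_grid)
        fractional_change_area(fc, coarse_grid) |>
          dplyr::mutate(method = m, .before = 1)
      })
    }
  }
  dplyr::bind_rows(
    dplyr::mutate(ref, method = "original", .before = 1),
    dplyr::bind_rows(rows)
  )
}
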