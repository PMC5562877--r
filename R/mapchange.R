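#' Declare a forest definition
#'
#' Three definition families recur across products: a set of categorical
#' class codes (IGBP forest classes 1-5, optionally plus woody savanna 8), a
#' percent-cover threshold applied to a fractional product, or raw
#' fractional cover itself (every non-zero cover fraction counts, area-
#' weighted). The choice shifts baseline forest area strongly, which is the
#' point of [definition_experiment()].
#'
#' @param kind `"class_set"`, `"cover_threshold"`, or `"fractional"`.
#' @param class_codes Integer class codes counted as forest
#'   (for `"class_set"`; default IGBP 1:5).
#' @param threshold_pct Percent-cover threshold in (0, 100\]
#'   (for `"cover_threshold"`).
#' @return A `forest_definition` object.
#' @examples
#' forest_definition("class_set")                       # IGBP forest classes
#' forest_definition("class_set", class_codes = c(1:5, 8))  # + woody savanna
#' forest_definition("cover_threshold", threshold_pct = 20)
#' @export
forest_definition <- function(kind = c("class_set", "cover_threshold",
                                       "fractional"),
                              class_codes = 1:5, threshold_pct = NULL) {
  kind <- match.arg(kind)
  if (kind == "class_set" && length(class_codes) == 0) {
    stop("`class_codes` must be non-empty for a class-set definition",
         call. = FALSE)
  }
  if (kind == "cover_threshold") {
    if (is.null(threshold_pct) || threshold_pct <= 0 || threshold_pct > 100) {
      stop("`threshold_pct` must lie in (0, 100]", call. = FALSE)
    }
  }
  structure(list(kind = kind,
                 class_codes = as.integer(class_codes),
                 threshold_pct = threshold_pct),
            class = "forest_definition")
}

#' Stable (modal) class map over a window of years
#'
#' Collapses an annual categorical series to its per-pixel modal class over
#' a window, suppressing spurious year-to-year label flicker before change
#' extraction. Ties are broken by `tie_rule`: `"latest"` (default) keeps the
#' tied class observed latest in the window; `"lowest"` keeps the smallest
#' code.
#'
#' @param cube Categorical [annual_cube()].
#' @param window Integer vector of calendar years (all within the cube span).
#' @param tie_rule `"latest"` or `"lowest"`.
#' @return Integer matrix of modal class codes.
#' @export
stable_class_map <- function(cube, window, tie_rule = c("latest", "lowest")) {
  tie_rule <- match.arg(tie_rule)
  yrs <- grid_years(cube$grid)
  idx <- match(window, yrs)
  if (length(idx) == 0 || anyNA(idx)) {
    stop("`window` must contain years present in the cube", call. = FALSE)
  }
  sub <- cube$values[, , idx, drop = FALSE]
  out <- apply(sub, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_integer_)
    counts <- table(v)
    top <- names(counts)[counts == max(counts)]
    if (length(top) == 1L) return(as.integer(top))
    if (tie_rule == "lowest") return(as.integer(min(as.numeric(top))))
    # latest-wins: the tied class whose last occurrence is most recent
    last_seen <- vapply(top, function(cl) max(which(v == as.numeric(cl))),
                        numeric(1))
    as.integer(top[which.max(last_seen)])
  })
  matrix(out, cube$grid$rows, cube$grid$cols)
}

#' Categorical change between two stable maps
#'
#' Post-classification change: loss where a forest pixel (under
#' `definition`) becomes non-forest, gain for the reverse, none otherwise.
#'
#' @param map_t1,map_t2 Integer class-code matrices for the two periods.
#' @param definition A class-set [forest_definition()].
#' @param grid The [grid_spec()] both maps live on.
#' @return A `change_map` (label layer only).
#' @export
categorical_change <- function(map_t1, map_t2,
                               definition = forest_definition("class_set"),
                               grid) {
  if (definition$kind != "class_set") {
    stop("categorical change needs a class-set definition", call. = FALSE)
  }
  if (!all(dim(map_t1) == dim(map_t2))) {
    stop("period maps differ in shape", call. = FALSE)
  }
  f1 <- matrix(map_t1 %in% definition$class_codes, nrow(map_t1))
  f2 <- matrix(map_t2 %in% definition$class_codes, nrow(map_t2))
  label <- matrix(0L, nrow(map_t1), ncol(map_t1))
  label[f1 & !f2] <- 1L
  label[!f1 & f2] <- 2L
  new_change_map(label, grid = grid)
}

#' Period-mean percent cover
#'
#' Per-pixel arithmetic mean of a percent-cover cube over a window of
#' years, skipping missing years; a pixel is NA only when every year in the
#' window is missing.
#'
#' @param cube Percent [annual_cube()].
#' @param window Integer vector of calendar years.
#' @return Numeric matrix of mean percent cover.
#' @export
period_mean_cover <- function(cube, window) {
  yrs <- grid_years(cube$grid)
  idx <- match(window, yrs)
  if (length(idx) == 0 || anyNA(idx)) {
    stop("`window` must contain years present in the cube", call. = FALSE)
  }
  sub <- cube$values[, , idx, drop = FALSE]
  out <- apply(sub, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  matrix(out, cube$grid$rows, cube$grid$cols)
}

#' Signed fractional cover change between two period means
#'
#' `delta = mean_t2 - mean_t1` in percent points; negative deltas feed the
#' loss component of fractional area accounting, positive deltas the gain
#' component.
#'
#' @param mean_t1,mean_t2 Percent matrices from [period_mean_cover()].
#' @param grid The shared [grid_spec()].
#' @return A `fraction_change` object wrapping the signed delta matrix.
#' @export
fractional_change <- function(mean_t1, mean_t2, grid) {
  if (!all(dim(mean_t1) == dim(mean_t2))) {
    stop("period maps differ in shape", call. = FALSE)
  }
  structure(list(delta = mean_t2 - mean_t1, grid = grid),
            class = "fraction_change")
}

#' @export
print.fraction_change <- function(x, ...) {
  cat(sprintf(
    "<fraction_change> %d x %d: %d loss px, %d gain px, mean delta %.3g\n",
    nrow(x$delta), ncol(x$delta),
    sum(x$delta < 0, na.rm = TRUE), sum(x$delta > 0, na.rm = TRUE),
    mean(x$delta, na.rm = TRUE)
  ))
  invisible(x)
}

#' Tidy a fractional change map
#' @param x A `fraction_change`.
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `delta`.
#' @method as_tibble fraction_change
#' @export
as_tibble.fraction_change <- function(x, ...) {
  tibble::tibble(
    row = rep(seq_len(nrow(x$delta)), times = ncol(x$delta)),
    col = rep(seq_len(ncol(x$delta)), each = nrow(x$delta)),
    delta = as.vector(x$delta)
  )
}

#' Binarize a percent-cover map under a cover-threshold definition
#'
#' @param percent_map Numeric percent matrix.
#' @param definition A cover-threshold [forest_definition()].
#' @return Logical matrix: forest where cover >= the threshold.
#' @export
binarize_cover <- function(percent_map, definition) {
  if (definition$kind != "cover_threshold") {
    stop("binarization needs a cover-threshold definition", call. = FALSE)
  }
  percent_map >= definition$threshold_pct
}

#' Accumulate annual binary loss layers
#'
#' A pixel is loss if a loss occurred during any year: logical OR across
#' the annual layers (so repeated flags never double count).
#'
#' @param loss_cube Binary [annual_cube()] of per-year loss flags.
#' @return Logical loss matrix.
#' @export
accumulate_annual_loss <- function(loss_cube) {
  apply(loss_cube$values, c(1, 2), function(v) any(v > 0, na.rm = TRUE))
}
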