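#' Simulate a ground-truth landscape
#'
#' Draws an event kind for every pixel i.i.d. from `mix` and assigns each a
#' change year, magnitude and ramp rate. The five kinds cover the change
#' classes a trajectory detector must separate: stable forest, stable
#' non-forest, abrupt loss (clearing/fire-like step), gradual gain
#' (afforestation ramp), and temporary loss followed by regrowth.
#' Event years are drawn uniformly on the interior of the year span so a
#' detector always has at least one observation on each side of the event.
#'
#' @param grid A [grid_spec()].
#' @param mix Named numeric vector of proportions over
#'   `c("stable_forest", "stable_nonforest", "abrupt_loss", "gradual_gain",
#'   "loss_then_recovery")`; must sum to 1 (tolerance 1e-9). Missing kinds
#'   default to 0.
#' @param magnitude Cover fraction removed by a loss event (or the saturation
#'   cover reached by a gain ramp), in \[0, 1\].
#' @param ramp_rate Cover fraction gained per year on gain/recovery ramps.
#' @param event_years Years the change events may fall on; defaults to the
#'   interior of the grid's span. Restrict this (e.g. to the years between
#'   two comparison windows) when a scene must be visible identically to
#'   window-based and trajectory-based recipes.
#' @param seed Integer seed; the scene is a deterministic function of
#'   (`grid`, `mix`, `seed`).
#'
#' @return A `truth_scene`: the grid plus a tibble of per-pixel event
#'   records (`row`, `col`, `kind`, `event_year`, `magnitude`, `ramp_rate`).
#' @examples
#' sc <- make_truth(grid_spec(8, 8), mix = c(stable_forest = 0.5,
#'                                           abrupt_loss = 0.5), seed = 1)
#' dplyr::count(sc$events, kind)
#' @export
make_truth <- function(grid,
                       mix = c(stable_forest = 0.40, stable_nonforest = 0.25,
                               abrupt_loss = 0.15, gradual_gain = 0.12,
                               loss_then_recovery = 0.08),
                       magnitude = 0.8, ramp_rate = 0.1,
                       event_years = NULL, seed = 1L) {
  kinds <- c("stable_forest", "stable_nonforest", "abrupt_loss",
             "gradual_gain", "loss_then_recovery")
  if (is.null(names(mix)) || !all(names(mix) %in% kinds)) {
    stop("`mix` must be named with known event kinds", call. = FALSE)
  }
  full_mix <- stats::setNames(numeric(length(kinds)), kinds)
  full_mix[names(mix)] <- mix
  if (abs(sum(full_mix) - 1) > 1e-9) {
    stop("`mix` proportions must sum to 1", call. = FALSE)
  }
  if (magnitude < 0 || magnitude > 1) {
    stop("`magnitude` must lie in [0, 1]", call. = FALSE)
  }
  n <- grid$rows * grid$cols
  yrs <- grid_years(grid)
  # interior years only: detection needs an observation on each side
  interior <- if (length(yrs) >= 3L) yrs[-c(1L, length(yrs))] else yrs
  if (!is.null(event_years)) {
    if (!all(event_years %in% interior)) {
      stop("`event_years` must lie strictly inside the year span",
           call. = FALSE)
    }
    interior <- as.integer(event_years)
  }
  events <- withr::with_seed(as.integer(seed), {
    kind <- sample(kinds, n, replace = TRUE, prob = full_mix)
    tibble::tibble(
      row = rep(seq_len(grid$rows), times = grid$cols),
      col = rep(seq_len(grid$cols), each = grid$rows),
      kind = kind,
      event_year = interior[sample.int(length(interior), n, replace = TRUE)],
      magnitude = magnitude,
      ramp_rate = ramp_rate
    )
  })
  events$event_year[events$kind %in% c("stable_forest", "stable_nonforest")] <-
    NA_integer_
  structure(list(grid = grid, events = events), class = "truth_scene")
}

#' @export
print.truth_scene <- function(x, ...) {
  cat(sprintf("<truth_scene> %d x %d pixels, years %d-%d\n",
              x$grid$rows, x$grid$cols, x$grid$year_start, x$grid$year_end))
  print(table(x$events$kind))
  invisible(x)
}

#' True fractional tree cover of a scene
#'
#' Evaluates the noiseless cover trajectory of every pixel:
#' stable forest sits at cover 1, stable non-forest at 0; abrupt loss drops
#' by `magnitude` at `event_year`; gradual gain climbs from 0 at `ramp_rate`
#' per year from `event_year` until it saturates at `magnitude`; loss-then-
#' recovery drops like abrupt loss and then regrows at `ramp_rate` per year,
#' capped at the pre-event cover.
#'
#' @param scene A [make_truth()] scene.
#' @return An [annual_cube()] of cover fractions in \[0, 1\]
#'   (`kind = "fraction"`).
#' @export
true_cover <- function(scene) {
  grid <- scene$grid
  yrs <- grid_years(grid)
  vals <- array(0, dim = c(grid$rows, grid$cols, length(yrs)))
  ev <- scene$events
  for (k in seq_len(nrow(ev))) {
    vals[ev$row[k], ev$col[k], ] <-
      cover_trajectory(ev$kind[k], ev$event_year[k], ev$magnitude[k],
                       ev$ramp_rate[k], yrs)
  }
  annual_cube(vals, grid, kind = "fraction")
}

cover_trajectory <- function(kind, event_year, magnitude, ramp_rate, years) {
  switch(kind,
    stable_forest = rep(1, length(years)),
    stable_nonforest = rep(0, length(years)),
    abrupt_loss = ifelse(years >= event_year, 1 - magnitude, 1),
    gradual_gain = pmin(magnitude,
                        pmax(0, (years - event_year + 1) * ramp_rate)),
    loss_then_recovery = {
      cov <- rep(1, length(years))
      post <- years >= event_year
      cov[post] <- pmin(1, (1 - magnitude) +
                          (years[post] - event_year) * ramp_rate)
      cov
    },
    stop("unknown event kind: ", kind, call. = FALSE)
  )
}
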