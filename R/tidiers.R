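#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted trajectory into per-segment rows
#'
#' @param x A [fit_trajectory()] result.
#' @param ... Unused.
#' @return Tibble with one row per segment: `segment`, `year_start`,
#'   `year_end`, `value_start`, `value_end`, `slope` (index units per
#'   year), `delta` (fitted value change over the segment).
#' @method tidy segment_fit
#' @export
tidy.segment_fit <- function(x, ...) {
  k <- length(x$slopes)
  tibble::tibble(
    segment = seq_len(k),
    year_start = x$vertex_years[seq_len(k)],
    year_end = x$vertex_years[seq_len(k) + 1L],
    value_start = x$vertex_values[seq_len(k)],
    value_end = x$vertex_values[seq_len(k) + 1L],
    slope = x$slopes,
    delta = diff(x$vertex_values)
  )
}

#' One-row summary of a fitted trajectory
#'
#' @param x A [fit_trajectory()] result.
#' @param ... Unused.
#' @return Tibble with `n_obs`, `n_segments`, `sse`, `rmse`.
#' @method glance segment_fit
#' @export
glance.segment_fit <- function(x, ...) {
  n <- length(x$series)
  tibble::tibble(
    n_obs = n,
    n_segments = length(x$slopes),
    sse = x$sse,
    rmse = sqrt(x$sse / n)
  )
}
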