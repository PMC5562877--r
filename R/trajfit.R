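#' Detector parameters for trajectory segmentation
#'
#' Bundles the user-facing knobs of the segmentation detector. The two
#' thresholds are in index units: `forest_threshold` separates forest from
#' non-forest index levels (a loss must start, and a gain must end, at or
#' above it), and `change_threshold` is the minimum absolute fitted index
#' change a segment must carry to count as change at all. Detection is
#' sensitive to both, which is why they are explicit here and swept in
#' [sweep_detector_params()].
#'
#' @param forest_threshold Index level at or above which a pixel counts as
#'   forest (default 0.4).
#' @param change_threshold Minimum absolute fitted segment change counted as
#'   change; must be > 0 (default 0.15).
#' @param max_segments Maximum number of linear segments in a fit
#'   (default 4).
#' @param despike_threshold Fraction of the local range a one-year excursion
#'   must exceed to be treated as a spike (default 0.5).
#' @param mse_improvement_min Minimum relative SSE improvement a new vertex
#'   must deliver to be kept (default 0.01).
#' @return A `detector_params` list.
#' @export
detector_params <- function(forest_threshold = 0.4, change_threshold = 0.15,
                            max_segments = 4L, despike_threshold = 0.5,
                            mse_improvement_min = 0.01) {
  if (change_threshold <= 0) {
    stop("`change_threshold` must be positive", call. = FALSE)
  }
  if (max_segments < 1L) stop("`max_segments` must be >= 1", call. = FALSE)
  structure(
    list(forest_threshold = forest_threshold,
         change_threshold = change_threshold,
         max_segments = as.integer(max_segments),
         despike_threshold = despike_threshold,
         mse_improvement_min = mse_improvement_min),
    class = "detector_params"
  )
}

#' Remove single-year spikes from an annual series
#'
#' An interior observation is a spike when it is a local extremum (both
#' neighbours lie on the same side) and even its smaller deviation from a
#' neighbour exceeds `threshold` times the local three-point range — a spike
#' must stand away from both neighbours, so the corner year of a genuine
#' step (which sits next to one of its neighbours) is never removed.
#' Spikes are replaced by the neighbour mean; comparisons use the original
#' values, so one pass is deterministic regardless of direction. Endpoints
#' are never touched, and a monotone step is never a spike.
#'
#' @param series Numeric vector of annual index values.
#' @param threshold Despike threshold in \[0, 1\] (fraction of local range).
#' @return Corrected series of identical length. Series shorter than 3 are
#'   returned unchanged.
#' @export
despike <- function(series, threshold = 0.5) {
  n <- length(series)
  if (n < 3L) return(series)
  out <- series
  for (i in 2:(n - 1)) {
    trio <- series[(i - 1):(i + 1)]
    if (anyNA(trio)) next
    m <- (trio[1] + trio[3]) / 2
    rng <- max(trio) - min(trio)
    is_extremum <- (trio[2] - trio[1]) * (trio[2] - trio[3]) > 0
    dev <- min(abs(trio[2] - trio[1]), abs(trio[2] - trio[3]))
    if (is_extremum && rng > 0 && dev > threshold * rng) {
      out[i] <- m
    }
  }
  out
}

# Least-squares continuous piecewise-linear fit for fixed interior vertices.
# Basis: intercept, time, and hinge terms max(0, t - v) per interior vertex.
pwl_fit <- function(y, t, interior) {
  X <- cbind(1, t)
  for (v in interior) X <- cbind(X, pmax(0, t - t[v]))
  fit <- stats::.lm.fit(X, y)
  fitted <- y - fit$residuals
  sse <- sum(fit$residuals^2)
  list(fitted = fitted, sse = sse)
}

#' Fit a continuous piecewise-linear trajectory
#'
#' Temporal segmentation of one pixel's annual index series: a continuous
#' piecewise-linear least-squares fit whose vertices mark disturbance or
#' recovery onsets. Vertices are chosen greedily top-down — starting from a
#' single segment, the interior year whose insertion reduces the SSE most is
#' added, followed by a coordinate-descent relocation pass over the current
#' vertices — until `max_segments` is reached or the SSE improvement of the
#' best insertion, relative to the single-segment fit's SSE, falls below
#' `mse_improvement_min` (judging improvements against the trajectory's own
#' variance scale stops vertex insertion from chasing noise once the
#' structure is captured).
#' The relocation pass lets an early, slightly misplaced split migrate onto
#' the true breakpoints, which makes the greedy search exact on noiseless
#' piecewise-linear input.
#'
#' @param series Numeric vector of annual index values (length >= 2, no NA).
#' @param years Calendar years of the observations (default consecutive).
#' @param max_segments Maximum number of linear segments.
#' @param mse_improvement_min Minimum relative SSE improvement to accept a
#'   new vertex.
#' @return A `segment_fit`: `vertex_years`, `vertex_values` (fitted values
#'   at the vertices), `slopes` (index units per year, one per segment),
#'   `fitted`, and `sse`.
#' @examples
#' fit <- fit_trajectory(c(rep(0.6, 6), rep(0.16, 8)), max_segments = 3)
#' tidy(fit)
#' @export
fit_trajectory <- function(series, years = NULL, max_segments = 4L,
                           mse_improvement_min = 0.01) {
  n <- length(series)
  if (n < 2L) stop("series must have at least 2 observations", call. = FALSE)
  if (anyNA(series)) stop("series must not contain NA", call. = FALSE)
  if (is.null(years)) years <- seq_len(n)
  t <- as.numeric(years)
  max_segments <- min(as.integer(max_segments), n - 1L)

  interior <- integer(0)           # indices into t, exclusive of endpoints
  best <- pwl_fit(series, t, interior)
  sse0 <- best$sse                 # single-segment SSE: the variance scale
  candidates <- setdiff(2:(n - 1), interior)

  while (length(interior) < max_segments - 1L && best$sse > 1e-12 &&
         length(candidates) > 0) {
    trial_sse <- vapply(candidates, function(v) {
      pwl_fit(series, t, sort(c(interior, v)))$sse
    }, numeric(1))
    k <- which.min(trial_sse)
    # improvement is judged against the single-segment SSE, so vertices that
    # only chase noise-scale residuals are rejected once the trajectory's
    # structure is captured; an insertion that makes the fit exact is always
    # kept (piecewise-linear input must be recovered exactly)
    improvement <- (best$sse - trial_sse[k]) / sse0
    exact <- trial_sse[k] <= 1e-9 * max(sse0, .Machine$double.eps)
    if (improvement < mse_improvement_min && !exact) break
    interior <- sort(c(interior, candidates[k]))
    # relocation pass: coordinate descent over vertex positions
    repeat {
      moved <- FALSE
      for (j in seq_along(interior)) {
        others <- interior[-j]
        pool <- setdiff(2:(n - 1), others)
        sse_j <- vapply(pool, function(v) {
          pwl_fit(series, t, sort(c(others, v)))$sse
        }, numeric(1))
        b <- which.min(sse_j)
        cur <- pwl_fit(series, t, interior)$sse
        if (sse_j[b] < cur - 1e-12) {
          interior <- sort(c(others, pool[b]))
          moved <- TRUE
        }
      }
      if (!moved) break
    }
    best <- pwl_fit(series, t, interior)
    candidates <- setdiff(2:(n - 1), interior)
  }

  vertex_idx <- c(1L, interior, n)
  vertex_years <- years[vertex_idx]
  vertex_values <- best$fitted[vertex_idx]
  slopes <- diff(vertex_values) / diff(as.numeric(vertex_years))
  structure(
    list(vertex_years = vertex_years, vertex_values = vertex_values,
         slopes = slopes, fitted = best$fitted, sse = best$sse,
         years = years, series = series),
    class = "segment_fit"
  )
}

#' @export
print.segment_fit <- function(x, ...) {
  cat(sprintf("<segment_fit> %d segment(s), sse = %.4g\n",
              length(x$slopes), x$sse))
  print(tidy(x))
  invisible(x)
}

#' Classify a fitted trajectory as loss, gain, or no change
#'
#' Candidate segments are those whose absolute fitted value change meets
#' `change_threshold`; the largest-magnitude candidate decides (ties go to
#' the earliest segment, for reproducibility). A negative decisive segment
#' is loss only if the segment starts at or above `forest_threshold` (it was
#' forest before losing); a positive one is gain only if it ends at or above
#' `forest_threshold` (it became forest). Otherwise the pixel is unchanged.
#'
#' @param fit A [fit_trajectory()] result.
#' @param params A [detector_params()].
#' @return One-row tibble: `label` (`"loss"`, `"gain"`, `"none"`),
#'   `change_year` (end year of a loss segment, start year of a gain
#'   segment; NA for none), `magnitude` (absolute fitted change; NA for
#'   none).
#' @export
classify_trajectory <- function(fit, params = detector_params()) {
  dv <- diff(fit$vertex_values)
  none <- tibble::tibble(label = "none", change_year = NA_integer_,
                         magnitude = NA_real_)
  cand <- which(abs(dv) >= params$change_threshold)
  if (length(cand) == 0) return(none)
  k <- cand[which.max(abs(dv[cand]))]   # which.max takes the first on ties
  if (dv[k] < 0) {
    if (fit$vertex_values[k] < params$forest_threshold) return(none)
    tibble::tibble(label = "loss",
                   change_year = as.integer(fit$vertex_years[k + 1]),
                   magnitude = abs(dv[k]))
  } else {
    if (fit$vertex_values[k + 1] < params$forest_threshold) return(none)
    tibble::tibble(label = "gain",
                   change_year = as.integer(fit$vertex_years[k]),
                   magnitude = abs(dv[k]))
  }
}

#' Detect forest change across an index cube
#'
#' The full per-pixel detector: gap-fill short runs of missing years
#' (linear interpolation over at most `max_gap` consecutive NAs), despike,
#' fit a piecewise-linear trajectory, and classify it. Loss labels outside
#' the forest mask are suppressed (the mask says where forest could have
#' been lost); gain labels are kept everywhere by default, since gain can
#' occur on previously non-forest land, but `mask_filters_gain = TRUE`
#' applies the mask to gain as well. Pixels with unfillable gaps are
#' labelled `none` and flagged in the QA layer.
#'
#' @param cube An [annual_cube()] of kind `"index"`.
#' @param params A [detector_params()].
#' @param mask Logical or 0/1 matrix matching the cube grid (TRUE = inside
#'   the forest domain); `NULL` means no masking.
#' @param mask_filters_gain Should the mask also suppress gain labels?
#' @param max_gap Longest run of consecutive missing years that is
#'   interpolated (default 2).
#' @return A `change_map`: integer `label` matrix (0 none, 1 loss, 2 gain),
#'   `year` and `magnitude` matrices, logical `qa` matrix of pixels excluded
#'   for missing data, the grid, and the parameters used.
#' @export
detect_changes <- function(cube, params = detector_params(), mask = NULL,
                           mask_filters_gain = FALSE, max_gap = 2L) {
  grid <- cube$grid
  if (!is.null(mask)) {
    if (!all(dim(mask) == c(grid$rows, grid$cols))) {
      stop("grid mismatch between cube and mask", call. = FALSE)
    }
    mask <- matrix(as.logical(mask), grid$rows, grid$cols)
  }
  yrs <- grid_years(grid)
  label <- matrix(0L, grid$rows, grid$cols)
  year <- matrix(NA_integer_, grid$rows, grid$cols)
  magnitude <- matrix(NA_real_, grid$rows, grid$cols)
  qa <- matrix(FALSE, grid$rows, grid$cols)

  for (i in seq_len(grid$rows)) {
    for (j in seq_len(grid$cols)) {
      s <- cube$values[i, j, ]
      if (anyNA(s)) {
        s <- fill_gaps(s, max_gap)
        if (anyNA(s)) { qa[i, j] <- TRUE; next }
      }
      s <- despike(s, params$despike_threshold)
      fit <- fit_trajectory(s, years = yrs,
                            max_segments = params$max_segments,
                            mse_improvement_min = params$mse_improvement_min)
      cls <- classify_trajectory(fit, params)
      if (cls$label == "loss") {
        if (!is.null(mask) && !mask[i, j]) next
        label[i, j] <- 1L
      } else if (cls$label == "gain") {
        if (mask_filters_gain && !is.null(mask) && !mask[i, j]) next
        label[i, j] <- 2L
      } else {
        next
      }
      year[i, j] <- cls$change_year
      magnitude[i, j] <- cls$magnitude
    }
  }
  new_change_map(label, year, magnitude, qa, grid, params)
}

# linear interpolation across interior NA runs of length <= max_gap;
# leading/trailing NAs are never filled
fill_gaps <- function(series, max_gap = 2L) {
  zoo::na.approx(series, na.rm = FALSE, maxgap = max_gap)
}

new_change_map <- function(label, year = NULL, magnitude = NULL, qa = NULL,
                           grid, params = NULL) {
  structure(
    list(label = label,
         year = if (is.null(year)) {
           matrix(NA_integer_, nrow(label), ncol(label))
         } else year,
         magnitude = if (is.null(magnitude)) {
           matrix(NA_real_, nrow(label), ncol(label))
         } else magnitude,
         qa = if (is.null(qa)) {
           matrix(FALSE, nrow(label), ncol(label))
         } else qa,
         grid = grid, params = params),
    class = "change_map"
  )
}

#' @export
print.change_map <- function(x, ...) {
  cat(sprintf(
    "<change_map> %d x %d: %d loss, %d gain, %d excluded (QA)\n",
    nrow(x$label), ncol(x$label),
    sum(x$label == 1L), sum(x$label == 2L), sum(x$qa)
  ))
  invisible(x)
}

#' Tidy a change map into a long tibble
#' @param x A `change_map`.
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `label` (factor none/loss/gain),
#'   `change_year`, `magnitude`, `qa`.
#' @method as_tibble change_map
#' @export
as_tibble.change_map <- function(x, ...) {
  tibble::tibble(
    row = rep(seq_len(nrow(x$label)), times = ncol(x$label)),
    col = rep(seq_len(ncol(x$label)), each = nrow(x$label)),
    label = factor(c("none", "loss", "gain")[as.vector(x$label) + 1L],
                   levels = c("none", "loss", "gain")),
    change_year = as.vector(x$year),
    magnitude = as.vector(x$magnitude),
    qa = as.vector(x$qa)
  )
}
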