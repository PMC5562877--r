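# Independent oracles and fixture builders shared across test files.

# Exhaustive piecewise-linear least squares: enumerate every interior vertex
# subset up to max_segments - 1 vertices and solve each continuous fit by QR
# on a hinge basis built here (independent of the package's fitter).
oracle_pwl_sse <- function(series, years = seq_along(series),
                           max_segments = 3L) {
  n <- length(series)
  t <- as.numeric(years)
  solve_sse <- function(interior) {
    X <- cbind(1, t)
    for (v in interior) X <- cbind(X, pmax(0, t - t[v]))
    beta <- qr.coef(qr(X), series)
    sum((series - X %*% beta)^2)
  }
  best <- solve_sse(integer(0))
  for (k in seq_len(max_segments - 1L)) {
    if (n - 2 < k) break
    combos <- utils::combn(2:(n - 1), k)
    for (c in seq_len(ncol(combos))) {
      best <- min(best, solve_sse(combos[, c]))
    }
  }
  best
}

# Deterministic family of noiseless piecewise-linear series of length n with
# at most 3 segments: every interior vertex pair (and singleton) crossed with
# a fixed set of vertex-level profiles.
pwl_series_family <- function(n = 14L) {
  t <- seq_len(n)
  levels2 <- list(c(0.6, 0.16), c(0.16, 0.6), c(0.1, 0.8))       # 1 vertex
  levels3 <- list(c(0.6, 0.6, 0.16), c(0.1, 0.7, 0.3),
                  c(0.6, 0.16, 0.16), c(0.2, 0.8, 0.5))          # 2 vertices
  series <- list()
  pwl_eval <- function(vt, vv) stats::approx(vt, vv, xout = t)$y
  for (a in 2:(n - 1)) {
    for (lv in levels2) {
      series[[length(series) + 1L]] <- pwl_eval(c(1, a, n),
                                                c(lv[1], lv[2], lv[2]))
    }
    if (a < n - 1) {
      for (b in (a + 1):(n - 1)) {
        for (lv in levels3) {
          series[[length(series) + 1L]] <-
            pwl_eval(c(1, a, b, n), c(lv[1], lv[2], lv[3], lv[3]))
        }
      }
    }
  }
  series
}

# A tiny deterministic scene shared by several end-to-end tests: a 10 x 10
# grid with known rectangles of each event kind (no randomness at all).
blocked_scene <- function(event_year = 2006L, magnitude = 0.8,
                          ramp_rate = 0.1) {
  g <- grid_spec(10, 10, pixel_size_m = 500)
  sc <- make_truth(g, mix = c(stable_forest = 1), seed = 1L)
  ev <- sc$events
  kind <- matrix("stable_forest", 10, 10)
  kind[1:3, 1:5] <- "abrupt_loss"
  kind[8:10, 1:4] <- "gradual_gain"
  kind[5:6, 8:10] <- "stable_nonforest"
  ev$kind <- kind[cbind(ev$row, ev$col)]
  ev$event_year <- ifelse(ev$kind %in% c("stable_forest",
                                         "stable_nonforest"),
                          NA_integer_, event_year)
  ev$magnitude <- magnitude
  ev$ramp_rate <- ramp_rate
  sc$events <- ev
  sc
}

truth_kind_matrix <- function(scene) {
  m <- matrix(NA_character_, scene$grid$rows, scene$grid$cols)
  m[cbind(scene$events$row, scene$events$col)] <- scene$events$kind
  m
}
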