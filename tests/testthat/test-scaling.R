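# independent direct-evaluation oracle for the separable kernels: each
# coarse cell is computed by an explicit 2-d tensor-product sum, with the
# kernel written out as the piecewise cubic polynomial
oracle_interp <- function(map, factor, kernel) {
  kern <- function(d) {
    d <- abs(d)
    if (kernel == "linear") return(ifelse(d < 1, 1 - d, 0))
    a <- -0.5
    ifelse(d <= 1, (a + 2) * d^3 - (a + 3) * d^2 + 1,
           ifelse(d < 2, a * (d^3 - 5 * d^2 + 8 * d - 4), 0))
  }
  nr <- nrow(map) %/% factor; nc <- ncol(map) %/% factor
  out <- matrix(0, nr, nc)
  reach <- if (kernel == "linear") 1 else 2
  for (I in seq_len(nr)) {
    for (J in seq_len(nc)) {
      pr <- (I - 0.5) * factor + 0.5    # position in fine centre coords
      pc <- (J - 0.5) * factor + 0.5
      acc <- 0
      for (k in (floor(pr) - reach + 1):(floor(pr) + reach)) {
        for (l in (floor(pc) - reach + 1):(floor(pc) + reach)) {
          kk <- min(nrow(map), max(1, k))   # border replication
          ll <- min(ncol(map), max(1, l))
          acc <- acc + kern(pr - k) * kern(pc - l) * map[kk, ll]
        }
      }
      out[I, J] <- acc
    }
  }
  out
}

test_that("block aggregation averages children and preserves mass", {
  m <- matrix(c(0, 100, 100, 100), 2)
  expect_equal(aggregate_average(m, 2), matrix(75, 1))
  const <- matrix(7, 6, 6)
  expect_equal(aggregate_average(const, 3), matrix(7, 2, 2))
  withr::with_seed(1, {
    big <- matrix(stats::runif(400), 20)
    expect_equal(mean(aggregate_average(big, 4)), mean(big),
                 tolerance = 1e-12)
  })
  # nodata-aware: mean of valid children, nodata only when all missing
  mna <- matrix(c(NA, 10, 20, NA), 2)
  expect_equal(aggregate_average(mna, 2), matrix(15, 1))
  allna <- matrix(NA_real_, 2, 2)
  expect_true(is.na(aggregate_average(allna, 2)[1, 1]))
  expect_error(aggregate_average(matrix(0, 3, 3), 2), "divisible")
})

test_that("binary-to-percent aggregation counts flagged children", {
  all_on <- matrix(1, 16, 16)
  expect_equal(aggregate_fraction(all_on, 16), matrix(100, 1))
  part <- matrix(0, 16, 16); part[1:8, 1:8] <- 1   # 64 of 256
  expect_equal(aggregate_fraction(part, 16), matrix(25, 1))
  expect_equal(aggregate_fraction(matrix(0, 4, 4), 4), matrix(0, 1))
})

test_that("resampling kernels match their definitions and reject invalid
           data kinds", {
  withr::with_seed(7, m <- matrix(stats::runif(144, 0, 100), 12))
  # nearest on a constant map is constant; factor 1 is the identity
  expect_equal(resample(matrix(3, 4, 4), 2, "nearest"), matrix(3, 2, 2))
  for (meth in c("nearest", "bilinear", "average", "mode", "cubic")) {
    expect_equal(resample(m, 1, meth), m)
  }
  # average == block aggregation by definition
  expect_equal(resample(m, 3, "average"), aggregate_average(m, 3))
  # mode takes the block majority
  mm <- matrix(c(1, 1, 1, 12), 2)
  expect_equal(resample(mm, 2, "mode", categorical = TRUE), matrix(1, 1))
  # bilinear and cubic agree with the direct tensor-product oracle
  expect_equal(resample(m, 2, "bilinear"),
               oracle_interp(m, 2, "linear"), tolerance = 1e-9)
  cub <- resample(m, 2, "cubic")
  orc <- oracle_interp(m, 2, "cubic")
  rng <- range(m)
  expect_equal(cub, pmin(pmax(orc, rng[1]), rng[2]), tolerance = 1e-9)
  # both reproduce a linear field exactly away from the borders
  lin <- outer(1:12, 1:12, `+`)
  expect_equal(resample(lin, 2, "bilinear"),
               outer(2 * (1:6) - 0.5, 2 * (1:6) - 0.5, `+`),
               tolerance = 1e-9)
  cubl <- resample(lin, 2, "cubic")
  expect_equal(cubl[2:5, 2:5],
               outer(2 * (2:5) - 0.5, 2 * (2:5) - 0.5, `+`),
               tolerance = 1e-9)
  expect_error(resample(mm, 2, "cubic", categorical = TRUE),
               "not suitable")
  expect_error(resample(mm, 2, "average", categorical = TRUE),
               "not suitable")
  expect_error(resample(mm, 2, "bilinear", categorical = TRUE),
               "not suitable")
})

# one 4x4 block pattern repeated over the grid: slight forest majority in
# period 1 (9 of 16), two conversions by period 2 (7 of 16), neither at the
# block centre the nearest/mode samplers see
scattered_conversion_maps <- function(n_blocks = 4L) {
  pat1 <- matrix(12, 4, 4)
  pat1[cbind(c(1, 1, 2, 2, 3, 3, 4, 4, 2),
             c(1, 4, 1, 2, 2, 3, 3, 4, 3))] <- 1   # 9 forest incl. centre
  pat2 <- pat1
  pat2[1, 1] <- 12; pat2[4, 4] <- 12               # 2 conversions off-centre
  t1 <- pat1[rep(1:4, n_blocks), rep(1:4, n_blocks)]
  t2 <- pat2[rep(1:4, n_blocks), rep(1:4, n_blocks)]
  list(t1 = t1, t2 = t2)
}

test_that("the two experiment orderings diverge as the block geometry
           dictates", {
  maps <- scattered_conversion_maps()
  g <- grid_spec(16, 16, pixel_size_m = 500)
  def <- forest_definition("class_set")

  stc <- run_scaling_experiment(maps, "scale_then_change", factor = 4,
                                grid = g, recipe = "categorical",
                                definition = def)
  ref <- stc$loss_km2[stc$method == "original"]
  # fine reference: 2 conversions per block, 16 blocks, 0.25 km2 pixels
  expect_equal(ref, 2 * 16 * 0.25)
  # modal reclassification flips whole blocks: every coarse pixel becomes
  # loss (majority forest -> majority non-forest)
  expect_equal(stc$loss_km2[stc$method == "mode"], 16 * 4)
  # the centre pixel never converts, so nearest sees no change at all
  expect_equal(stc$loss_km2[stc$method == "nearest"], 0)

  cm_fine <- categorical_change(maps$t1, maps$t2, def, g)
  cts <- run_scaling_experiment(cm_fine, "change_then_scale", factor = 4,
                                grid = g)
  # averaging the change map preserves the area exactly (linearity)
  expect_equal(cts$loss_km2[cts$method == "average"], ref,
               tolerance = 1e-9)
  # across methods, resampling the change map deviates less from the
  # reference than re-extracting change from resampled maps
  dev <- function(tab) max(abs(tab$loss_km2[tab$method != "original"] - ref))
  expect_lt(dev(cts), dev(stc))
})

test_that("experiment tables are reproducible one method at a time", {
  maps <- scattered_conversion_maps()
  g <- grid_spec(16, 16, pixel_size_m = 500)
  fc <- fractional_change(100 * (maps$t1 == 1), 100 * (maps$t2 == 1), g)
  tab <- run_scaling_experiment(fc, "change_then_scale", factor = 4,
                                grid = g, methods = c("average", "nearest"))
  # each row equals a direct resample + accounting call
  cg <- coarsen_grid(g, 4)
  direct <- sum(resample(pmax(-fc$delta, 0) / 100, 4, "average")) *
    pixel_area_km2(cg)
  expect_equal(tab$loss_km2[tab$method == "average"], direct)
  expect_equal(tab$loss_km2[tab$method == "original"],
               fractional_change_area(fc, g)$loss_km2)
})
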