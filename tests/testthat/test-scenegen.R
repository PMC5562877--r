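test_that("truth scenes honour the event mix, bounds and determinism", {
  g <- grid_spec(10, 10)
  sc <- make_truth(g, mix = c(stable_forest = 1), seed = 3)
  expect_equal(nrow(sc$events), 100)
  expect_true(all(sc$events$kind == "stable_forest"))
  cov <- true_cover(sc)
  expect_true(all(cov$values == 1))

  sc2 <- make_truth(g, mix = c(abrupt_loss = 1), magnitude = 0.8, seed = 3)
  cov2 <- true_cover(sc2)$values
  # every pixel drops by exactly 0.8 at its event year
  for (k in sample(nrow(sc2$events), 10)) {
    e <- sc2$events[k, ]
    traj <- cov2[e$row, e$col, ]
    yrs <- grid_years(g)
    expect_equal(traj[yrs < e$event_year], rep(1, sum(yrs < e$event_year)))
    expect_equal(traj[yrs >= e$event_year],
                 rep(0.2, sum(yrs >= e$event_year)))
  }
  # event years stay off the endpoints
  expect_true(all(sc2$events$event_year > g$year_start &
                    sc2$events$event_year < g$year_end))

  # determinism: same seed, same scene; cover always within [0, 1]
  sc3 <- make_truth(g, mix = c(abrupt_loss = 1), magnitude = 0.8, seed = 3)
  expect_identical(sc2$events, sc3$events)
  mixed <- make_truth(g, seed = 11)
  expect_true(all(true_cover(mixed)$values >= 0 &
                    true_cover(mixed)$values <= 1))

  expect_error(make_truth(g, mix = c(stable_forest = 0.7)), "sum to 1")
  expect_error(grid_spec(0, 5), "at least one")
})

test_that("trajectory shapes per event kind are as constructed", {
  yrs <- 2000:2013
  expect_equal(cover_trajectory("gradual_gain", 2005, 0.6, 0.1, yrs),
               pmin(0.6, pmax(0, (yrs - 2004) * 0.1)))
  rec <- cover_trajectory("loss_then_recovery", 2006, 0.8, 0.1, yrs)
  expect_equal(rec[yrs < 2006], rep(1, 6))
  expect_equal(rec[yrs == 2006], 0.2)
  expect_true(all(diff(rec[yrs >= 2006]) >= 0) && max(rec) <= 1)
})

test_that("index rendering is the affine map of cover plus bounded noise", {
  sc <- blocked_scene()
  nbr0 <- render_nbr(sc, level_forest = 0.6, level_bare = 0.05, sigma = 0)
  # stable forest pixel: 0.6 every year
  expect_equal(nbr0$values[5, 5, ], rep(0.6, 14))
  # abrupt loss pixel steps 0.6 -> 0.05 + 0.55 * 0.2 = 0.16 at the event
  expect_equal(nbr0$values[1, 1, ], c(rep(0.6, 6), rep(0.16, 8)))

  # noise s.d. recovered over many pixel-years (law of large numbers)
  g <- grid_spec(30, 30)
  scf <- make_truth(g, mix = c(stable_forest = 1), seed = 5)
  nbr <- render_nbr(scf, sigma = 0.02, seed = 9)
  resid <- nbr$values - 0.6
  expect_lt(abs(stats::sd(resid) - 0.02), 0.001)
  expect_true(all(nbr$values >= -1 & nbr$values <= 1))
  expect_error(render_nbr(sc, sigma = -1), "non-negative")
  expect_error(render_nbr(sc, level_forest = 0.1, level_bare = 0.5),
               "exceed")
})

test_that("categorical rendering thresholds cover and flips labels at the
           stated rate", {
  sc <- blocked_scene()
  lc <- render_lc(sc, flip_prob = 0)
  expect_equal(lc$values[5, 5, ], rep(1, 14))            # stable forest
  expect_equal(lc$values[1, 1, ], c(rep(1, 6), rep(12, 8)))  # loss at 2006
  expect_equal(lc$values[5, 9, ], rep(12, 14))           # stable non-forest

  g <- grid_spec(30, 30)
  scf <- make_truth(g, mix = c(stable_forest = 1), seed = 5)
  lcn <- render_lc(scf, flip_prob = 0.1, seed = 2)
  n_flipped <- sum(lcn$values == 12)
  n_total <- length(lcn$values)
  # binomial expectation within 3 s.d.
  expect_lt(abs(n_flipped - 0.1 * n_total),
            3 * sqrt(n_total * 0.1 * 0.9))
  expect_error(render_lc(sc, flip_prob = 1), "flip_prob")
})

test_that("fractional cover rendering refines the grid and is unbiased", {
  sc <- blocked_scene()
  v0 <- render_vcf(sc, refine_factor = 2, sigma_pct = 0)
  expect_equal(v0$grid$rows, 20)
  expect_equal(v0$grid$pixel_size_m, 250)
  # noiseless children replicate the parent percent exactly
  expect_equal(v0$values[1:2, 1:2, 14], matrix(20, 2, 2))  # post-loss 0.2
  expect_equal(v0$values[9, 9, 1], 100)                    # stable forest

  g <- grid_spec(25, 25)
  scf <- make_truth(g, mix = c(stable_forest = 1), seed = 5)
  vn <- render_vcf(scf, refine_factor = 2, sigma_pct = 5, seed = 4)
  # clipping at 100 truncates the upper noise tail, so compare against the
  # mean of a truncated gaussian rather than raw truth
  sims <- pmin(100, pmax(0, 100 + 5 * stats::rnorm(1e5)))
  expect_lt(abs(mean(vn$values) - mean(sims)), 0.1)
  expect_error(render_vcf(sc, refine_factor = 0), "refine_factor")
})

test_that("fine loss/gain rendering counts children and years correctly", {
  sc <- blocked_scene(event_year = 2006L)
  gfc <- render_gfc(sc, refine_factor = 4, forest_threshold = 0.5)
  yrs <- grid_years(sc$grid)
  # each abrupt-loss parent contributes 16 children in the event-year layer
  layer_2006 <- cube_layer(gfc$loss, 2006L)
  expect_equal(sum(layer_2006), 15 * 16)          # 15 loss parents
  expect_equal(sum(gfc$loss$values), 15 * 16)     # and in no other year
  # gain layer marks the gradual-gain parents, loss layers stay clear there
  expect_equal(sum(gfc$gain), 12 * 16)            # 12 gain parents
  all_stable <- make_truth(grid_spec(5, 5), mix = c(stable_forest = 1),
                           seed = 1)
  gfc0 <- render_gfc(all_stable, refine_factor = 2)
  expect_equal(sum(gfc0$loss$values), 0)
  expect_equal(sum(gfc0$gain), 0)
  expect_equal(gfc$baseline[1, 1], 100)           # year-2000 percent cover
})

test_that("province partition tiles the grid and conserves area", {
  g <- grid_spec(10, 10)
  pr <- render_provinces(g, 2, 2)
  expect_equal(sort(unique(as.vector(pr$raster))), 1:4)
  expect_equal(as.vector(table(pr$raster)), rep(25, 4))
  expect_equal(sum(pr$table$land_area_km2), 100 * 0.25)
  pr1 <- render_provinces(g, 1, 1)
  expect_true(all(pr1$raster == 1))
  # non-divisible grids still partition completely
  g2 <- grid_spec(7, 5)
  pr2 <- render_provinces(g2, 3, 2)
  expect_equal(sum(pr2$table$land_area_km2),
               7 * 5 * pixel_area_km2(g2))
})
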