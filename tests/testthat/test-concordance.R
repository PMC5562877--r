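test_that("binary change flags honour labels and the non-zero delta rule", {
  g <- grid_spec(2, 2)
  lab <- matrix(c(1L, 2L, 0L, 1L), 2)
  cm <- forestflux:::new_change_map(lab, grid = g)
  expect_equal(to_binary_change(cm, "loss"), lab == 1L)
  expect_equal(to_binary_change(cm, "gain"), lab == 2L)
  fc <- structure(list(delta = matrix(c(-0.3, 0, 12, -80), 2), grid = g),
                  class = "fraction_change")
  expect_equal(to_binary_change(fc, "loss"),
               matrix(c(TRUE, FALSE, FALSE, TRUE), 2))
  expect_equal(to_binary_change(fc, "gain"),
               matrix(c(FALSE, FALSE, TRUE, FALSE), 2))
})

test_that("agreement counts, banding and composition match hand counts", {
  f1 <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2)
  f2 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  f3 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2)
  f4 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2)
  ag <- agreement_count(list(a = f1, b = f2, c = f3, d = f4), "loss")
  expect_equal(ag$count, matrix(c(4L, 2L, 1L, 0L), 2))
  expect_equal(as.character(agreement_category(ag$count)),
               c("high", "low", "low", "none"))
  # level counts partition the pixels flagged by at least one dataset
  flagged <- f1 | f2 | f3 | f4
  expect_equal(sum(ag$count > 0), sum(flagged))

  comp <- agreement_composition(ag, list(a = f1, b = f2, c = f3, d = f4))
  # dataset a flags 3 pixels at levels 4, 2, 1 -> one third each
  a_row <- comp[comp$dataset == "a", ]
  expect_equal(a_row$pct, c(100 / 3, 100 / 3, 0, 100 / 3))
  expect_equal(sum(a_row$pct), 100)
  # dataset c flags a single pixel, and all four agree there
  expect_equal(comp$pct[comp$dataset == "c"], c(0, 0, 0, 100))
})

test_that("plain correlation and its t-test match the closed form and a
           reference implementation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_true(pearson_cor(x, 2 * x + 1)$significant)
  # residualized vector is exactly orthogonal
  y <- c(2, 1, 4, 3, 6)
  y_perp <- stats::residuals(stats::lm(y ~ x))
  expect_equal(pearson_cor(x, y_perp)$r, 0, tolerance = 1e-12)
  # borderline case: n = 31, r = 0.30 is just under the 90% critical value
  withr::with_seed(2, {
    repeat {
      a <- stats::rnorm(31); b0 <- stats::rnorm(31)
      # construct a vector with exact sample correlation 0.30
      b <- 0.30 * scale(a)[, 1] +
        sqrt(1 - 0.09) * scale(stats::residuals(stats::lm(b0 ~ a)))[, 1]
      if (abs(stats::cor(a, b) - 0.30) < 1e-12) break
    }
    res <- pearson_cor(a, b)
    expect_equal(res$t, 0.30 * sqrt(29 / (1 - 0.09)), tolerance = 1e-9)
    expect_false(res$significant)
    # cross-check r and the p-value machinery against cor.test
    ct <- stats::cor.test(a, b, conf.level = 0.90)
    expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$significant, ct$p.value < 0.10)
  })
  # zero variance: undefined, not significant
  z <- pearson_cor(rep(1, 5), x)
  expect_true(is.na(z$r))
  expect_false(z$significant)
})

test_that("weighted correlation reduces to plain r under equal weights and
           is weight-scale invariant", {
  withr::with_seed(3, {
    x <- stats::rnorm(20); y <- 0.5 * x + stats::rnorm(20)
    w <- stats::runif(20, 1, 10)
  })
  expect_equal(weighted_pearson(x, y, rep(2, 20))$r,
               pearson_cor(x, y)$r, tolerance = 1e-12)
  expect_equal(weighted_pearson(x, y, w)$r,
               weighted_pearson(x, y, 1000 * w)$r, tolerance = 1e-12)
  # Kish effective n equals n at equal weights
  expect_equal(weighted_pearson(x, y, rep(2, 20))$n_eff, 20)
  # a dominant weight drives |r| towards 1 (two effective points)
  xw <- c(0, 1, 2, 3); yw <- c(5, -2, 7, 1)
  r_dom <- weighted_pearson(xw, yw, c(1e6, 1, 1, 1e6))$r
  expect_gt(abs(r_dom), 0.999)
  expect_error(weighted_pearson(x, y, rep(0, 20)), "zero")
})

test_that("the correlation matrix is symmetric with unit diagonal and
           respects missing datasets per metric", {
  withr::with_seed(4, {
    latent <- stats::rnorm(12)
    tabs <- purrr::map(c(a = 1, b = 2, c = 3), function(s) {
      tibble::tibble(province_id = 1:12,
                     value = latent + stats::rnorm(12, sd = 0.1),
                     weight = stats::runif(12, 1, 5))
    }) |> dplyr::bind_rows(.id = "dataset")
  })
  cmx <- correlation_matrix(tabs)
  expect_equal(diag(cmx$r), c(a = 1, b = 1, c = 1))
  expect_equal(cmx$r, t(cmx$r))
  # one shared latent pattern: all off-diagonals significant positive
  off <- cmx$r[upper.tri(cmx$r)]
  expect_true(all(off > 0.9))
  expect_true(all(cmx$significant))

  # a dataset with no values for the metric yields NA cells, not an error
  tabs_na <- dplyr::bind_rows(
    tabs, tibble::tibble(dataset = "nfi", province_id = 1:12,
                         value = NA_real_, weight = 1))
  cmx_na <- correlation_matrix(tabs_na)
  expect_true(all(is.na(cmx_na$r["nfi", c("a", "b", "c")])))

  # weighted path agrees with the unweighted one at constant weight
  tabs$weight <- 1
  cw <- correlation_matrix(tabs, weighted = TRUE)
  expect_equal(cw$r, cmx$r, tolerance = 1e-12)
  td <- tidy(cmx)
  expect_equal(nrow(td), 6)   # 3 diagonal + 3 upper cells
})
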