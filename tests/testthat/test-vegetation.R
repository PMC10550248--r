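test_that("negative index values are clamped to zero with bookkeeping", {
  obs <- data.frame(cell_id = "c1", date = as.Date("2020-01-01") + 0:4,
                    evi = c(-0.1, 0.3, 0, -0.05, 0.6), site = "north")
  cl <- clamp_nonnegative(obs)
  expect_equal(cl$evi, c(0, 0.3, 0, 0, 0.6))
  expect_equal(attr(cl, "n_clamped"), 2L)
})

test_that("seasonal anomalies standardize each cell-month to mean 0, sd 1", {
  # hand-computed instance: one month observed across three years
  obs <- data.frame(
    cell_id = "c1",
    date = as.Date(c("2019-03-10", "2020-03-10", "2021-03-10")),
    evi = c(1, 2, 3), site = "north"
  )
  an <- seasonal_anomaly(obs)
  expect_equal(an$delta_evi, c(-1, 0, 1))  # sample sd of {1,2,3} is 1
  # general synthetic series: every cell-month group is standardized
  series <- gen_evi(evi_sim_spec(n_cells_per_site = 2,
                                 start = "2015-01-01", end = "2020-12-31"),
                    seed = 5)
  an2 <- seasonal_anomaly(clamp_nonnegative(series))
  key <- interaction(an2$cell_id, an2$month, drop = TRUE)
  mus <- tapply(an2$delta_evi, key, mean)
  sds <- tapply(an2$delta_evi, key, sd)
  expect_lt(max(abs(mus)), 1e-10)
  expect_lt(max(abs(sds - 1)), 1e-10)
})

test_that("degenerate and undersized month groups are handled explicitly", {
  # exactly periodic series: zero sd per month, anomalies 0 and flagged
  dates <- seq(as.Date("2018-01-01"), as.Date("2020-12-31"), by = 16)
  obs <- data.frame(cell_id = "c1", date = dates,
                    evi = 0.2, site = "south")
  an <- seasonal_anomaly(obs)
  expect_true(all(an$delta_evi == 0))
  expect_true(all(an$sd_zero_flag))
  # a single observation in a month group names the cell and month
  obs2 <- data.frame(cell_id = "c9",
                     date = as.Date(c("2020-05-01", "2019-06-01",
                                      "2020-06-01")),
                     evi = c(0.1, 0.2, 0.3), site = "north")
  expect_error(seasonal_anomaly(obs2), "c9")
})

test_that("anomalies are invariant to per-month shifts and positive rescaling", {
  series <- gen_evi(evi_sim_spec(n_cells_per_site = 1,
                                 start = "2016-01-01", end = "2020-12-31"),
                    seed = 9)
  base <- seasonal_anomaly(series)
  shifted <- series
  shifted$evi <- shifted$evi +
    0.3 * as.integer(format(shifted$date, "%m"))  # constant per month
  rescaled <- shifted
  rescaled$evi <- 2.7 * rescaled$evi
  expect_equal(seasonal_anomaly(shifted)$delta_evi, base$delta_evi,
               tolerance = 1e-10)
  expect_equal(seasonal_anomaly(rescaled)$delta_evi, base$delta_evi,
               tolerance = 1e-10)
})

test_that("moving-window smoothing averages consecutive composites", {
  dates <- seq(as.Date("2020-01-01"), by = 16, length.out = 6)
  an <- data.frame(cell_id = "c1", date = dates, site = "north",
                   delta_evi = c(0, 1, 2, 3, 4, 5))
  sm <- moving_window(an, window = 6)
  expect_equal(sm$w_smoothed[1], 2.5)
  expect_true(all(is.na(sm$w_smoothed[-1])))  # window no longer fits
  # window = 1 is the identity
  sm1 <- moving_window(an, window = 1)
  expect_equal(sm1$w_smoothed, an$delta_evi)
  # constant anomalies smooth to the same constant
  an$delta_evi <- 0.7
  expect_true(all(moving_window(an, window = 3)$w_smoothed[1:4] == 0.7))
  # window longer than the series warns and leaves NA
  expect_warning(out <- moving_window(an, window = 7), "longer")
  expect_true(all(is.na(out$w_smoothed)))
})

test_that("randomization test is null-calibrated on identical series", {
  x <- rnorm(50)
  res <- randomization_median_test(x, x, n_iter = 499, seed = 1)
  expect_equal(res$observed, 0)
  expect_gte(res$p, 0.95)
  expect_lte(res$ci_low, res$ci_high)
  expect_length(res$null_draws, 499)
  expect_error(randomization_median_test(numeric(0), x), "at least one")
  expect_warning(randomization_median_test(x, x, n_iter = 50, seed = 1),
                 "unstable")
})

test_that("sampled p-values agree with exhaustive enumeration on 4 points", {
  south <- c(10, 11); north <- c(0, 1)
  ex <- randomization_median_test(south, north, exhaustive = TRUE)
  # oracle: all 4!/(2!2!) = 6 splits enumerated by hand
  pool <- c(south, north)
  splits <- combn(4, 2)
  draws <- apply(splits, 2, function(i) median(pool[i]) - median(pool[-i]))
  expect_equal(sort(ex$null_draws), sort(draws))
  expect_equal(ex$p, mean(abs(draws) >= 10))  # exactly 2 of 6
  # Monte-Carlo version converges to the exhaustive p
  mc <- randomization_median_test(south, north, n_iter = 9999, seed = 2)
  expect_lt(abs(mc$p - ex$p), 0.02)
})

test_that("full-shuffle p is invariant to site relabeling", {
  set.seed(11)
  a <- rnorm(40, 0.4)
  b <- rnorm(40)
  p_ab <- randomization_median_test(a, b, n_iter = 1999, seed = 5)$p
  p_ba <- randomization_median_test(b, a, n_iter = 1999, seed = 6)$p
  expect_lt(abs(p_ab - p_ba), 0.05)
})

test_that("a site contrast at the observed anomaly scale is detected", {
  # shift the south anomalies by 1.0 within-cell sd; rejection rate > 0.9
  spec <- evi_sim_spec(n_cells_per_site = 1,
                       start = "2016-01-01", end = "2020-12-31")
  rejections <- vapply(1:20, function(r) {
    an <- seasonal_anomaly(clamp_nonnegative(gen_evi(spec, seed = 100 + r)))
    south <- an$delta_evi[an$site == "south"] + 1.0
    north <- an$delta_evi[an$site == "north"]
    randomization_median_test(south, north, n_iter = 199, seed = r)$p < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.9)
})

test_that("within-time-swap mode flips aligned site labels per composite", {
  set.seed(12)
  x <- rnorm(60); y <- rnorm(60) + 1
  res <- randomization_median_test(y, x, n_iter = 499, seed = 3,
                                   mode = "within_time_swap")
  expect_lt(res$p, 0.05)
  expect_error(
    randomization_median_test(y, x[1:10], mode = "within_time_swap"),
    "aligned")
})
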