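test_that("ARIMA selection reproduces deterministic series exactly", {
  # a drifted random walk reproduces a deterministic line exactly
  y <- 0.1 + 0.002 * (0:19)
  sel <- select_arima(y)
  expect_equal(sel$order[2], 1L)
  expect_lt(max(abs(sel$fitted[-1] - y[-1])), 1e-6)
  expect_equal(sel$fitted[1], y[1])
  # constant series: every fitted value is the constant
  selc <- select_arima(rep(0.1, 20))
  expect_true(all(abs(selc$fitted - 0.1) < 1e-12))
  # length and NA pattern are preserved
  y2 <- ar1_series(20, 0.1, 0.002, 0.5, 0.01, seed = 4)
  y2[c(3, 11)] <- NA
  sel2 <- select_arima(y2)
  expect_length(sel2$fitted, 20)
  expect_identical(is.na(sel2$fitted), is.na(y2))
})

test_that("median regression is exact on collinear points and L1-optimal otherwise", {
  yr <- 2003:2022
  ml <- median_line(yr, 0.1 + 0.002 * (yr - 2003))
  expect_equal(ml$slope, 0.002, tolerance = 1e-12)
  expect_equal(ml$intercept + ml$slope * 2003, 0.1, tolerance = 1e-9)
  # constant input
  expect_equal(median_line(yr, rep(1, 20))$slope, 0)
  # sign-flip equivariance
  set.seed(8)
  y <- 0.1 + 0.002 * (yr - 2003) + rnorm(20, 0, 0.01)
  a <- median_line(yr, y); b <- median_line(yr, -y)
  expect_equal(a$slope, -b$slope, tolerance = 1e-12)
  expect_equal(a$intercept, -b$intercept, tolerance = 1e-12)
  # L1 optimality against an independent numerical minimiser (multi-start)
  for (k in 1:5) {
    yk <- rnorm(20, 0, 1)
    fit <- median_line(yr, yk)
    ours <- l1_objective(c(fit$intercept, fit$slope), yr, yk)
    for (start in list(c(0, 0), c(mean(yk), 0), c(0, 0.1))) {
      opt <- optim(start, l1_objective, x = yr, y = yk,
                   control = list(maxit = 5000, reltol = 1e-12))
      expect_lte(ours, opt$value + 1e-8)
    }
  }
})

test_that("rank-score CI brackets the slope, flips sign, and is calibrated on iid data", {
  yr <- 2003:2022
  set.seed(9)
  y <- 0.1 + 0.002 * (yr - 2003) + rnorm(20, 0, 0.005)
  ml <- median_line(yr, y); ci <- rank_ci(yr, y)
  expect_lte(ci$ci_low, ml$slope)
  expect_gte(ci$ci_high, ml$slope)
  nci <- rank_ci(yr, -y)
  expect_equal(nci$ci_low, -ci$ci_high, tolerance = 1e-12)
  expect_equal(nci$ci_high, -ci$ci_low, tolerance = 1e-12)
  # exactly collinear data give a degenerate interval at the true slope
  cic <- rank_ci(yr, 0.1 + 0.002 * (yr - 2003))
  expect_equal(cic$ci_low, 0.002, tolerance = 1e-9)
  expect_equal(cic$ci_high, 0.002, tolerance = 1e-9)
  # constant response: CI contains 0
  ci0 <- rank_ci(yr, rep(0.3, 20))
  expect_true(ci0$ci_low <= 0 && ci0$ci_high >= 0)
  # level: on iid noise the rejection rate stays near (below) nominal
  rej <- replicate(400, {
    ci <- rank_ci(yr, rnorm(20))
    ci$ci_low > 0 || ci$ci_high < 0
  })
  expect_lte(mean(rej), 0.10)
})

test_that("classification follows the CI rule and endpoint predictions follow the line", {
  yr <- 2003:2022
  # significant increase: endpoints from the regression line
  f <- fit_kd_trend(0.1 + 0.002 * (yr - 2003), yr)
  expect_equal(f$classification, "increasing")
  expect_equal(f$kd_end - f$kd_start, 0.002 * 19, tolerance = 1e-9)
  # decreasing case is symmetric
  fd <- fit_kd_trend(0.2 - 0.002 * (yr - 2003), yr)
  expect_equal(fd$classification, "decreasing")
  expect_equal(fd$kd_end - fd$kd_start, -0.002 * 19, tolerance = 1e-9)
  # no significant change: both endpoints are the raw-series median
  # (a trendless alternating series cannot be classified significant)
  y0 <- 0.1 + 0.01 * rep(c(1, -1), 10)
  f0 <- fit_kd_trend(y0, yr)
  expect_equal(f0$classification, "no_change")
  expect_equal(f0$kd_start, max(0.01, median(y0)))
  expect_equal(f0$kd_start, f0$kd_end)
  # too few valid years
  yna <- c(rep(NA, 12), y0[13:20])
  expect_equal(fit_kd_trend(yna, yr)$classification, "insufficient_data")
})

test_that("tidy and glance expose the fit in broom form", {
  f <- fit_kd_trend(0.1 + 0.002 * (0:19), 2003:2022)
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "conf.low", "conf.high"))
  expect_equal(td$estimate[td$term == "slope"], 0.002, tolerance = 1e-9)
  gl <- glance(f)
  expect_equal(gl$arima_d, 1L)
  expect_equal(gl$classification, "increasing")
})

test_that("the pixel map recovers planted slopes and is worker-invariant", {
  g <- small_grid(6)
  slope <- matrix(seq(-0.004, 0.004, length.out = 36), 6, 6)
  stk <- simulate_kd_stack(g, baseline = 0.3, slope = slope, sigma = 0,
                           dropout = 0, seed = 1)
  tr1 <- kd_trends(stk)
  truth <- attr(stk, "truth")
  expect_equal(tr1$slope, truth$true_slope, tolerance = 1e-3)
  # worker count does not change any output
  tr2 <- kd_trends(stk, workers = 2)
  expect_equal(as.data.frame(tr1), as.data.frame(tr2))
  # an all-missing pixel is insufficient_data, and does not abort the map
  stk$kd[stk$pixel == 14] <- NA
  tr3 <- kd_trends(stk)
  expect_equal(tr3$classification[tr3$pixel == 14], "insufficient_data")
  expect_equal(glance(tr3)$n_insufficient, 1L)
})
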