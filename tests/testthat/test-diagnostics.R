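test_that("rate of change is the lag-1 difference of MFT and telescopes", {
  s <- population_series("A", c("2010-01", "2010-02"),
                         ftd = c(5 / 31, 5 / 28))
  # equal monthly counts -> zero rate
  s$mft <- c(1, 1); s$monthly_count <- exp(1) - 1
  r <- rate_of_change(s)
  expect_equal(r$r, 0)

  # counts 5 -> 0: rate is -ln(6)
  s2 <- population_series("A", c("2010-01", "2010-02"), ftd = c(5 / 31, 0),
                          days = c(31, 28))
  s2$monthly_count <- c(5, 0); s2$mft <- log(c(6, 1))
  expect_equal(rate_of_change(s2)$r, -log(6))

  # telescoping over a contiguous stretch
  set.seed(9)
  s3 <- population_series("A", sprintf("2010-%02d", 1:8), ftd = runif(8))
  r3 <- rate_of_change(s3)
  expect_equal(sum(r3$r), s3$mft[8] - s3$mft[1], tolerance = 1e-12)
  expect_equal(r3$mft_lag, s3$mft[1:7])
})

test_that("gaps break the rate series instead of differencing across them", {
  s <- population_series("A", c("2010-01", "2010-02", "2010-04", "2010-05"),
                         ftd = c(1, 2, 3, 4))
  r <- rate_of_change(s)
  expect_equal(format(r$month, "%Y-%m"), c("2010-02", "2010-05"))
  expect_equal(diff(r$time), 3L)

  # missing month (recorded NA) also breaks the chain
  s2 <- population_series("A", sprintf("2010-%02d", 1:4),
                          ftd = c(1, NA, 3, 4))
  expect_equal(nrow(rate_of_change(s2)), 1)
  expect_error(rate_of_change(population_series("A", c("2010-01", "2010-03"),
                                                c(1, 2))),
               "no adjacent pair")
})

test_that("linear trend test matches OLS and its degenerate cases", {
  tr <- linear_trend_test(2 * (1:20) + 3)
  expect_equal(tr$slope, 2)
  expect_equal(tr$adj_r_squared, 1)
  expect_lt(tr$p_value, 1e-12)

  # values orthogonal to time: slope 0
  v <- rep(c(1, -1), 10)
  tr2 <- linear_trend_test(v, rep(1:2, 10))
  expect_equal(tr2$slope, -2)
  expect_error(linear_trend_test(1:5, rep(2, 5)), "singular|constant")

  # white noise: adjusted R^2 near 0 and roughly uniform p-values
  set.seed(4)
  ps <- replicate(300, linear_trend_test(rnorm(70))$p_value)
  expect_lt(abs(mean(ps) - 0.5), 0.06)
  expect_lt(abs(mean(ps < 0.25) - 0.25), 0.07)
})

test_that("detrending preserves the mean of the rates", {
  r <- c(1, 2, 3)
  tr <- linear_trend_test(r, 1:3)
  expect_equal(detrend_rate(r, tr), c(2, 2, 2))

  set.seed(5)
  rate <- make_rate(40)
  tr2 <- linear_trend_test(rate$r, rate$time)
  d <- detrend_rate(rate, tr2)
  expect_equal(mean(d), mean(rate$r), tolerance = 1e-12)

  # zero-slope trend leaves the series unchanged
  v <- c(1, -1, -1, 1)
  expect_equal(detrend_rate(v, linear_trend_test(v, 1:4)), v)

  expect_error(detrend_rate(c(1, 2), tr), "length")
})

test_that("sample ACF uses the biased denominator and standard bounds", {
  set.seed(6)
  x <- rnorm(200)
  a <- a_stats <- acf(x, lag.max = 10, plot = FALSE)$acf[2:11]
  mine <- acf_corr(x, 10)
  expect_equal(mine$value, a_stats, tolerance = 1e-12)
  expect_equal(mine$bound, rep(1.96 / sqrt(200), 10))

  # strictly alternating series: lag-1 correlation tends to -1
  alt <- rep(c(1, -1), 250)
  expect_lt(acf_corr(alt, 1)$value, -0.99)

  # AR(1) simulation: acf approximates phi^k
  set.seed(7)
  y <- as.numeric(arima.sim(list(ar = 0.6), 5000))
  expect_lt(max(abs(acf_corr(y, 5)$value - 0.6^(1:5))), 0.05)

  expect_error(acf_corr(rep(3, 50), 5), "constant")
  expect_error(acf_corr(rnorm(10), 10), "max_lag")
})

test_that("PACF agrees with stats and with the lag-regression oracle", {
  set.seed(8)
  x <- as.numeric(arima.sim(list(ar = 0.6), 5000))
  p <- pacf_corr(x, 6)
  # same convention as stats::pacf (Durbin-Levinson on biased ACF)
  expect_equal(p$value, drop(pacf(x, lag.max = 6, plot = FALSE)$acf),
               tolerance = 1e-10)
  # lag 1 equals the lag-1 ACF; AR(1) cuts off after lag 1
  expect_equal(p$value[1], acf_corr(x, 1)$value)
  expect_lt(abs(p$value[2]), 2 * 2 / sqrt(5000))

  # brute-force regression oracle, random series
  set.seed(9)
  for (i in 1:20) {
    z <- as.numeric(arima.sim(list(ar = runif(1, -0.7, 0.7),
                                   ma = runif(1, -0.5, 0.5)), 400))
    expect_lt(max(abs(pacf_corr(z, 4)$value - pacf_by_regression(z, 4))),
              0.02)
  }
})

test_that("PRCF replaces lag 1 by the rate correlation and keeps higher lags", {
  set.seed(10)
  mft_lag <- rnorm(120, 3, 1)
  r <- -0.9 * mft_lag + rnorm(120, sd = 0.1)
  d <- detrend_rate(r, linear_trend_test(r, 1:120))
  pr <- prcf(d, mft_lag, 5)
  expect_lt(pr$value[1], -0.9)
  expect_equal(pr$value[1], cor(d, mft_lag))
  # lags >= 2 bit-identical to the PACF of the same input
  expect_identical(pr$value[-1], pacf_corr(d, 5)$value[-1])

  expect_error(prcf(d, rep(2, 120), 5), "constant")
  expect_error(prcf(d, mft_lag[-1], 5), "aligned")
})

test_that("VIF matches the closed form and flags collinearity", {
  n <- 100
  # exactly orthogonal mean-zero columns
  e1 <- c(rep(1, 50), rep(-1, 50)); e2 <- rep(c(1, -1), 50)
  expect_equal(unname(vif(cbind(e1, e2))), c(1, 1), tolerance = 1e-10)

  # exact correlation 0.9 -> VIF = 1/(1-0.81)
  x2 <- 0.9 * e1 + sqrt(1 - 0.81) * e2
  expect_equal(unname(vif(cbind(e1, x2))), rep(1 / (1 - 0.81), 2),
               tolerance = 1e-8)

  expect_true(all(is.infinite(vif(cbind(e1, e1)))))
  expect_error(vif(cbind(e1)), "2 columns")
})

test_that("diagnose_series runs the full chain on the longest stretch", {
  rate <- make_rate(48, seed = 11)
  dg <- diagnose_series(rate_parent <- gen_population(
    sim_config(n_months = 48), seed = 11))
  expect_named(dg, c("rate", "trend", "detrended", "acf", "prcf"))
  expect_equal(dg$acf$lag, dg$prcf$lag)
  expect_identical(dg$prcf$value[-1], pacf_corr(dg$detrended,
                                                max(dg$acf$lag))$value[-1])
})
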