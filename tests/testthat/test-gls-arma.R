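test_that("theoretical ARMA autocorrelations match closed forms and stats", {
  # AR(1): rho_k = phi^k
  expect_equal(arma_acf(0.5, numeric(0), 4), 0.5^(0:4))
  # MA(1): rho_1 = theta/(1+theta^2), zero beyond
  expect_equal(arma_acf(numeric(0), 0.4, 3), c(1, 0.4 / 1.16, 0, 0))
  # ARMA(1,1) recursion: rho_2 = phi * rho_1
  r11 <- arma_acf(0.5, 0.3, 2)
  expect_equal(r11[3], 0.5 * r11[2])

  # random stationary parameter sets against the reference implementation
  set.seed(12)
  for (i in 1:20) {
    p <- sample(0:2, 1); q <- sample(0:2, 1)
    if (p + q == 0) q <- 1
    phi <- pacf_to_coef_test(runif(p, -0.9, 0.9))
    theta <- pacf_to_coef_test(runif(q, -0.9, 0.9))
    expect_equal(arma_acf(phi, theta, 10),
                 unname(ARMAacf(ar = phi, ma = theta, lag.max = 10)),
                 tolerance = 1e-10)
  }

  expect_error(arma_acf(c(1.2), numeric(0), 3), "stationary")
  expect_error(arma_acf(c(0.5, 0.6), numeric(0), 3), "root")
})

test_that("the stationarity transform round-trips and stays in-region", {
  for (z in list(0.7, c(0.3, -0.8), c(1.5, -0.2, 0.4))) {
    co <- oliverate:::uncons_to_coef(z)
    expect_silent(oliverate:::check_stationary(co))
    expect_equal(oliverate:::coef_to_uncons(co), z, tolerance = 1e-8)
  }
})

test_that("simulated ARMA noise reproduces the specified moments", {
  set.seed(13)
  x <- sim_arma(1e5, 0.5, numeric(0), sd = 1)
  # stationary SD of AR(1): sd/sqrt(1-phi^2)
  expect_equal(sd(x), 1 / sqrt(1 - 0.25), tolerance = 0.02)
  expect_lt(max(abs(acf_corr(x, 3)$value - 0.5^(1:3))), 0.02)
})

test_that("build_sigma composes correlation and variance weights", {
  d <- data.frame(y = rnorm(4), time = c(1, 2, 3, 5),
                  g = factor(c("a", "a", "b", "b")), v = c(1, 4, 9, 16))
  sp <- gls_spec(y ~ 1)
  expect_equal(build_sigma(sp, d)$sigma0, diag(4))

  # two strata with SD ratio 2 -> variances 1 and 4
  sp2 <- gls_spec(y ~ 1, variance = variance_structure(strata = "g"))
  sg <- build_sigma(sp2, d, ratios = list(g = c(a = 1, b = 2)))
  expect_equal(diag(sg$sigma0), c(1, 1, 4, 4))

  # covariate-proportional variance
  sp3 <- gls_spec(y ~ 1, variance = variance_structure(covariate = "v"))
  expect_equal(diag(build_sigma(sp3, d)$sigma0), c(1, 4, 9, 16))
  d_bad <- d; d_bad$v[1] <- -1
  expect_error(build_sigma(sp3, d_bad), "positive")

  # gap between rows 3 and 4 (separation 2): AR(1) corr 0.25
  sg4 <- build_sigma(sp, d, phi = 0.5)
  expect_equal(sg4$R[3, 4], 0.25)
  expect_equal(sg4$R[1, 2], 0.5)
  # adjacency option ignores the gap
  sg5 <- build_sigma(sp, d, phi = 0.5, gap_handling = "adjacent")
  expect_equal(sg5$R[3, 4], 0.5)
})

test_that("profiled likelihood is permutation invariant and matches the dense oracle", {
  rate <- make_rate(20, seed = 14)
  sp <- gls_spec(arma = c(1, 0))
  ll <- gls_loglik(sp, rate, phi = 0.4)
  perm <- sample(nrow(rate))
  expect_equal(gls_loglik(sp, rate[perm, ], phi = 0.4), ll, tolerance = 1e-10)

  # dense multivariate-normal oracle, ML and REML, n <= 15
  set.seed(15)
  for (i in 1:10) {
    n <- sample(8:15, 1)
    d <- make_rate(n + 6, seed = 100 + i)[1:n, ]
    phi <- runif(1, -0.6, 0.6); theta <- runif(1, -0.6, 0.6)
    sp2 <- gls_spec(arma = c(1, 1),
                    variance = variance_structure(strata = "season"))
    mf <- oliverate:::prepare_model_frame(sp2, d)
    lev <- levels(droplevels(mf$data$season))
    ratios <- list(season = setNames(c(1, runif(length(lev) - 1, 0.5, 2)),
                                     lev))
    sg <- build_sigma(sp2, mf$data, phi, theta, ratios)
    for (m in c("ML", "REML")) {
      expect_equal(gls_loglik(sp2, d, phi = phi, theta = theta,
                              ratios = ratios, method = m),
                   dense_mvn_loglik(mf$y, mf$X, sg$sigma0, m),
                   tolerance = 1e-8)
    }
  }
})

test_that("GLS reduces to OLS without correlation or variance structure", {
  rate <- make_rate(50, seed = 16)
  f <- fit_gls(gls_spec(arma = c(0, 0), method = "REML"), rate)
  ols <- lm(r ~ mft_lag + nlst + naoi + fruit, data = rate)
  expect_equal(unname(coef(f)), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(f$coefficients$se, unname(sqrt(diag(vcov(ols)))),
               tolerance = 1e-8)
  expect_equal(f$sigma, summary(ols)$sigma, tolerance = 1e-8)
  # and ML coefficients are identical (scale convention differs only in SE)
  fml <- fit_gls(gls_spec(arma = c(0, 0), method = "ML"), rate)
  expect_equal(unname(coef(fml)), unname(coef(ols)), tolerance = 1e-8)
})

test_that("ARMA parameters are recovered consistently on long series", {
  d <- make_regression_frame(n = 800, phi = 0.5, sd = 0.5, seed = 17)
  f <- fit_gls(gls_spec(arma = c(1, 0)), d,
               gls_control(restarts = 0, reltol = 1e-8))
  expect_lt(abs(f$phi - 0.5), 0.05)
  expect_lt(abs(coef(f)["mft_lag"] - (-0.5)), 0.05)
  # fitted rho sequence matches the empirical ACF of a long simulation
  set.seed(18)
  long <- sim_arma(2e5, f$phi, f$theta)
  expect_lt(max(abs(arma_acf(f$phi, f$theta, 5)[-1] -
                      acf_corr(long, 5)$value)), 0.02)
})

test_that("REML estimates are invariant to recentring covariates", {
  d <- make_regression_frame(n = 80, phi = 0.4, seed = 19)
  f1 <- fit_gls(gls_spec(arma = c(1, 0), method = "REML"), d,
                gls_control(restarts = 0))
  d2 <- d; d2$nlst <- d2$nlst + 100
  f2 <- fit_gls(gls_spec(arma = c(1, 0), method = "REML"), d2,
                gls_control(restarts = 0))
  keep <- c("mft_lag", "nlst", "naoi", "fruit")
  expect_equal(coef(f1)[keep], coef(f2)[keep], tolerance = 1e-6)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
})

test_that("BIC counts every estimated parameter and ranks structures sanely", {
  d <- make_regression_frame(n = 60, phi = 0.5, seed = 20)
  f0 <- fit_gls(gls_spec(arma = c(0, 0)), d)
  f1 <- fit_gls(gls_spec(arma = c(1, 0)), d, gls_control(restarts = 0))
  expect_equal(f0$n_par, 6) # 5 beta + sigma
  expect_equal(f1$n_par, 7)
  expect_equal(f1$BIC, -2 * f1$logLik + 7 * log(f1$n))

  # true AR(1) structure beats under- and over-specification most of the time
  set.seed(21)
  wins <- 0L
  for (i in 1:40) {
    di <- make_regression_frame(n = 60, phi = 0.5, seed = 3000 + i)
    b_true <- fit_gls(gls_spec(arma = c(1, 0)), di,
                      gls_control(restarts = 0, reltol = 1e-8))$BIC
    b_under <- fit_gls(gls_spec(arma = c(0, 0)), di)$BIC
    b_over <- fit_gls(gls_spec(arma = c(2, 2)), di,
                      gls_control(restarts = 0, reltol = 1e-8))$BIC
    if (b_true < b_under && b_true < b_over) wins <- wins + 1L
  }
  expect_gte(wins / 40, 0.8)
})

test_that("degenerate designs raise descriptive errors, non-convergence is flagged", {
  d <- make_regression_frame(n = 30, seed = 22)
  d$dup <- d$mft_lag
  expect_error(fit_gls(gls_spec(r ~ mft_lag + dup), d), "singular")
  expect_error(fit_gls(gls_spec(), d[1:4, ]), "parameters")
  # serialization carries the structure description
  f <- fit_gls(gls_spec(arma = c(1, 0)), d, gls_control(restarts = 0))
  tab <- fit_to_table(f)
  expect_true(all(c("estimate", "se", "p", "BIC", "variance") %in% names(tab)))
  js <- jsonlite::fromJSON(fit_to_json(f))
  expect_equal(js$spec$arma, c(1, 0))
  expect_equal(js$logLik, f$logLik)
})

test_that("the engine agrees with the reference GLS implementation", {
  d <- make_regression_frame(n = 90, phi = 0.5, theta = 0.3, sd = 0.5,
                             seed = 23)
  f <- fit_gls(gls_spec(arma = c(1, 1), method = "ML"), d,
               gls_control(restarts = 1))
  g <- nlme::gls(r ~ mft_lag + nlst + naoi + fruit, data = d,
                 correlation = nlme::corARMA(form = ~time, p = 1, q = 1),
                 method = "ML")
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-4)
  expect_equal(f$logLik, as.numeric(logLik(g)), tolerance = 1e-6)

  fs <- fit_gls(gls_spec(arma = c(1, 0), method = "REML",
                         variance = variance_structure(strata = "season")),
                d, gls_control(restarts = 1))
  gs <- nlme::gls(r ~ mft_lag + nlst + naoi + fruit, data = d,
                  correlation = nlme::corAR1(form = ~time),
                  weights = nlme::varIdent(form = ~1 | season),
                  method = "REML")
  expect_equal(unname(coef(fs)), unname(coef(gs)), tolerance = 1e-4)
  expect_equal(fs$logLik, as.numeric(logLik(gs)), tolerance = 1e-6)
  expect_equal(fs$coefficients$se, unname(sqrt(diag(vcov(gs)))),
               tolerance = 1e-4)
})
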