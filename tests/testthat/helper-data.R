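# shared fixture builders; everything is generated in code

# a small observed rate series from the synthetic generator
make_rate <- function(n_months = 60, phi = 0.5, sigma_u = 0, seed = 123, ...) {
  cfg <- sim_config(n_months = n_months, phi = phi, sigma_u = sigma_u, ...)
  rate_of_change(gen_population(cfg, seed = seed))
}

# regression-style frame with exogenous predictors and ARMA errors: the
# covariates do not feed back on the response, so GLS assumptions hold
# exactly
make_regression_frame <- function(n = 120, phi = 0.5, theta = numeric(0),
                                  sd = 0.5, seed = 1,
                                  beta = c(1.5, -0.5, -0.02, 0.13, 0.8)) {
  set.seed(seed)
  cfg <- sim_config(n_months = n + 1, seed = seed)
  cov <- gen_covariates(cfg)
  eps <- sim_arma(n, phi, theta, sd = sd)
  mft_lag <- rnorm(n, 3, 1)
  data.frame(
    r = beta[1] + beta[2] * mft_lag + beta[3] * cov$nlst[1:n] +
      beta[4] * cov$naoi[1:n] + beta[5] * cov$fruit[1:n] + eps,
    mft_lag = mft_lag, nlst = cov$nlst[1:n], naoi = cov$naoi[1:n],
    fruit = cov$fruit[1:n],
    season = season_of(cov$month_of_year[1:n]),
    year = factor(format(cov$month, "%Y")[1:n]),
    time = seq_len(n))
}

# dense multivariate-normal profiled log-likelihood, computed the direct
# way (solve/det), independent of the package's Cholesky/profile path
dense_mvn_loglik <- function(y, X, sigma0, method = "ML") {
  n <- length(y); k <- ncol(X)
  Si <- solve(sigma0)
  beta <- solve(t(X) %*% Si %*% X, t(X) %*% Si %*% y)
  r <- y - X %*% beta
  rss <- drop(t(r) %*% Si %*% r)
  if (method == "ML") {
    s2 <- rss / n
    -n / 2 * log(2 * pi) - 0.5 * determinant(sigma0)$modulus[1] -
      n / 2 * log(s2) - n / 2
  } else {
    s2 <- rss / (n - k)
    -(n - k) / 2 * log(2 * pi) - 0.5 * determinant(sigma0)$modulus[1] -
      0.5 * determinant(t(X) %*% Si %*% X)$modulus[1] -
      (n - k) / 2 * log(s2) - (n - k) / 2
  }
}

# brute-force partial autocorrelation at lag k: last coefficient of the
# OLS regression of x_t on (x_{t-1}, ..., x_{t-k})
pacf_by_regression <- function(x, max_lag) {
  n <- length(x)
  vapply(seq_len(max_lag), function(k) {
    Y <- x[(k + 1):n]
    X <- sapply(seq_len(k), function(j) x[(k + 1 - j):(n - j)])
    unname(coef(lm(Y ~ X))[k + 1])
  }, numeric(1))
}

# stationary coefficients from partial autocorrelations (test-side alias)
pacf_to_coef_test <- function(pac) oliverate:::pacf_to_coef(pac)
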