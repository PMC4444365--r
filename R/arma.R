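# ---- ARMA(p,q) process utilities -------------------------------------------
# The GLS engine models residual correlation as a stationary, invertible
# ARMA(p,q) process in discrete (monthly) time. Everything here works with
# the AR coefficients phi (length p) and MA coefficients theta (length q) in
# the x_t = sum phi_i x_{t-i} + e_t + sum theta_j e_{t-j} convention.

# check that the polynomial 1 - phi_1 z - ... - phi_p z^p has all roots
# outside the unit circle
check_stationary <- function(phi, what = "AR") {
  if (length(phi) == 0) return(invisible(TRUE))
  r <- polyroot(c(1, -phi))
  bad <- Mod(r) <= 1 + 1e-10
  if (any(bad)) {
    stop(sprintf("%s parameters outside the stationary/invertible region: root modulus %.4f <= 1",
                 what, min(Mod(r))), call. = FALSE)
  }
  invisible(TRUE)
}

# MA(infinity) psi-weights of an ARMA(p,q); psi_0 = 1. The recursion
# psi_j = theta_j + sum_i phi_i psi_{j-i} is an AR filter applied to the
# theta-extended impulse, so stats::filter does it in C.
psi_weights <- function(phi, theta, n) {
  x <- c(1, theta, rep(0, max(0, n - length(theta))))[1:(n + 1)]
  if (length(phi) == 0) return(x)
  as.numeric(filter(x, phi, method = "recursive"))
}

#' Theoretical autocorrelations of a stationary ARMA(p,q) process
#'
#' Computes \eqn{\rho_k} for \eqn{k = 0, \dots, max\_lag} from the MA(inf)
#' representation: \eqn{\gamma_k = \sigma^2 \sum_j \psi_j \psi_{j+k}} with the
#' psi-weights accumulated until they are numerically negligible. These are
#' the correlations the GLS engine places between residuals separated by k
#' months.
#'
#' @param phi AR coefficients (may be empty).
#' @param theta MA coefficients (may be empty).
#' @param max_lag largest lag required.
#' @return numeric vector \code{rho[0..max_lag]} with \code{rho[1] == 1}
#'   (R indexing: element \code{k+1} is lag \code{k}).
#' @export
#' @examples
#' arma_acf(phi = 0.5, theta = numeric(0), max_lag = 3) # 0.5^k
arma_acf <- function(phi, theta, max_lag) {
  phi <- as.numeric(phi); theta <- as.numeric(theta)
  check_stationary(phi, "AR")
  p <- length(phi); q <- length(theta)
  if (p == 0 && q == 0) return(c(1, rep(0, max_lag)))
  # exact autocovariances (sigma^2 = 1): solve the linear equations
  #   gamma(k) - sum_i phi_i gamma(|k-i|) = b_k,  k = 0..p
  # with b_k = sum_{j=k}^{q} theta_j psi_{j-k} (theta_0 = 1), then recurse
  # gamma(k) = sum_i phi_i gamma(k-i) + b_k for k > p
  th <- c(1, theta)
  psi <- psi_weights(phi, theta, q)
  b <- vapply(0:max(p, max_lag), function(k) {
    if (k > q) 0 else sum(th[(k + 1):(q + 1)] * psi[1:(q + 1 - k)])
  }, numeric(1))
  A <- matrix(0, p + 1, p + 1)
  for (k in 0:p) {
    A[k + 1, k + 1] <- A[k + 1, k + 1] + 1
    for (i in seq_len(p))
      A[k + 1, abs(k - i) + 1] <- A[k + 1, abs(k - i) + 1] - phi[i]
  }
  gamma <- numeric(max(max_lag, p) + 1)
  gamma[1:(p + 1)] <- solve(A, b[1:(p + 1)])
  if (max_lag > p) {
    for (k in (p + 1):max_lag) {
      g <- b[k + 1]
      for (i in seq_len(p)) g <- g + phi[i] * gamma[k - i + 1]
      gamma[k + 1] <- g
    }
  }
  gamma <- gamma[1:(max_lag + 1)]
  gamma / gamma[1]
}

# ---- stationarity-preserving parameterization ------------------------------
# Optimization over phi/theta runs in an unconstrained space: z in R^p maps
# through tanh to partial autocorrelations in (-1,1), which map through the
# Durbin-Levinson step to a stationary AR polynomial (Monahan's transform,
# as used by arima()). The same map enforces invertibility for theta.

pacf_to_coef <- function(pac) {
  p <- length(pac)
  if (p == 0) return(numeric(0))
  a <- pac[1]
  if (p > 1) for (k in 2:p) a <- c(a - pac[k] * rev(a), pac[k])
  a
}

coef_to_pacf <- function(coef) {
  p <- length(coef)
  if (p == 0) return(numeric(0))
  pac <- numeric(p)
  a <- coef
  for (k in p:1) {
    pac[k] <- a[k]
    if (k > 1) {
      denom <- 1 - a[k]^2
      if (denom <= 0) stop("coefficients not in the stationary region",
                           call. = FALSE)
      a <- (a[-k] + a[k] * rev(a[-k])) / denom
    }
  }
  pac
}

# clamp away from +-1 so the optimizer cannot reach the boundary exactly
uncons_to_coef <- function(z) pacf_to_coef(pmin(pmax(tanh(z), -0.9999), 0.9999))
coef_to_uncons <- function(coef) atanh(pmin(pmax(coef_to_pacf(coef), -0.999999),
                                            0.999999))

#' Simulate a Gaussian ARMA(p,q) series
#'
#' Direct recursive simulation (independent of \code{\link{arma_acf}}),
#' used for the process noise of the synthetic generator and for
#' calibration experiments. A burn-in is discarded so the series starts
#' near stationarity.
#'
#' @param n length of the returned series.
#' @param phi,theta ARMA parameters.
#' @param sd innovation standard deviation.
#' @param burn burn-in length discarded.
#' @return numeric vector of length \code{n}.
#' @export
sim_arma <- function(n, phi, theta, sd = 1, burn = 200L) {
  p <- length(phi); q <- length(theta)
  m <- n + burn
  e <- rnorm(m, sd = sd)
  x <- numeric(m)
  for (t in seq_len(m)) {
    v <- e[t]
    for (j in seq_len(min(q, t - 1))) v <- v + theta[j] * e[t - j]
    for (i in seq_len(min(p, t - 1))) v <- v + phi[i] * x[t - i]
    x[t] <- v
  }
  x[(burn + 1):m]
}
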