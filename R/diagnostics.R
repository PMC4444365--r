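#' Rate of population change (R-function)
#'
#' The per-capita rate of change on the log scale,
#' \eqn{R_t = MFT_t - MFT_{t-1}}, i.e. the lag-1 difference of the log
#' monthly abundance. Differences are only taken between calendar-adjacent
#' months with observed abundance; a gap (missing month) breaks the series
#' rather than producing a difference across it.
#'
#' @param series a \code{population_series}.
#' @return a \code{data.frame} of class \code{rate_series} with one row per
#'   computable rate: \code{month} (of \eqn{t}), \code{r}, \code{mft_lag}
#'   (\eqn{MFT_{t-1}}), the time-\eqn{t} covariates \code{nlst, naoi, fruit,
#'   season, year}, and \code{time} (integer month index, for true time
#'   separations across gaps).
#' @export
rate_of_change <- function(series) {
  stopifnot(inherits(series, "population_series"))
  n <- nrow(series)
  if (sum(!is.na(series$mft)) < 2)
    stop("need at least 2 non-missing months to compute rates", call. = FALSE)
  idx <- month_index(series$month)
  keep <- logical(n)
  for (t in 2:n) {
    keep[t] <- !is.na(series$mft[t]) && !is.na(series$mft[t - 1]) &&
      idx[t] == idx[t - 1] + 1L
  }
  if (!any(keep))
    stop("no adjacent pair of observed months: cannot compute rates",
         call. = FALSE)
  t_idx <- which(keep)
  out <- data.frame(
    site = series$site[t_idx], month = series$month[t_idx],
    r = series$mft[t_idx] - series$mft[t_idx - 1L],
    mft_lag = series$mft[t_idx - 1L],
    nlst = series$nlst[t_idx], naoi = series$naoi[t_idx],
    fruit = series$fruit[t_idx], season = series$season[t_idx],
    year = series$year[t_idx], time = idx[t_idx],
    stringsAsFactors = FALSE)
  class(out) <- c("rate_series", "data.frame")
  out
}

# longest run of consecutive time indices in a rate series
longest_stretch <- function(rate) {
  stopifnot(inherits(rate, "rate_series"))
  if (nrow(rate) == 1) return(rate)
  brk <- cumsum(c(0, diff(rate$time) != 1L))
  runs <- split(seq_len(nrow(rate)), brk)
  lens <- lengths(runs)
  rate[runs[[which.max(lens)]], , drop = FALSE]
}

#' Linear trend test
#'
#' Ordinary least-squares regression of a series on time, used to check for
#' temporal trends in the rate of change (and in covariate series). Reports
#' the slope, adjusted R-squared, F statistic on (1, n-2) df and its p-value.
#'
#' @param values numeric response.
#' @param time_index numeric time axis (default 1..n).
#' @return list of class \code{trend_result} with \code{slope, intercept,
#'   adj_r_squared, f_statistic, p_value, residuals, n}.
#' @export
linear_trend_test <- function(values, time_index = seq_along(values)) {
  ok <- !is.na(values) & !is.na(time_index)
  y <- values[ok]; x <- time_index[ok]
  if (length(y) < 3) stop("need n >= 3 for a trend test", call. = FALSE)
  if (length(unique(x)) < 2)
    stop("constant time index: singular design", call. = FALSE)
  fit <- lm(y ~ x)
  s <- suppressWarnings(summary(fit)) # perfect fits are legitimate inputs
  res <- rep(NA_real_, length(values))
  res[ok] <- resid(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 adj_r_squared = s$adj.r.squared,
                 f_statistic = unname(s$fstatistic[1]),
                 p_value = unname(pf(s$fstatistic[1], s$fstatistic[2],
                                     s$fstatistic[3], lower.tail = FALSE)),
                 residuals = res, mean_value = mean(y), n = length(y)),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Linear trend: slope %.4g, adj R^2 %.3f, F(1,%d) = %.3f, p = %.3g\n",
              x$slope, x$adj_r_squared, x$n - 2, x$f_statistic, x$p_value))
  invisible(x)
}

#' Detrend a rate series
#'
#' Removes the fitted linear temporal trend while preserving the level:
#' trend residuals plus the mean of the original rates, so the detrended
#' series has the same mean as the input.
#'
#' @param rate a \code{rate_series} (or numeric vector of rates).
#' @param trend a \code{trend_result} fitted on these rates (fitted when
#'   omitted).
#' @return numeric vector of detrended rates.
#' @export
detrend_rate <- function(rate, trend = NULL) {
  r <- if (inherits(rate, "rate_series")) rate$r else as.numeric(rate)
  tt <- if (inherits(rate, "rate_series")) rate$time else seq_along(r)
  if (is.null(trend)) trend <- linear_trend_test(r, tt)
  if (length(trend$residuals) != length(r))
    stop("trend was not fitted on this rate series (length mismatch)",
         call. = FALSE)
  trend$residuals + mean(r, na.rm = TRUE)
}

# sample autocovariance with the biased (1/n) denominator
sample_acov <- function(x, max_lag) {
  n <- length(x)
  xc <- x - mean(x)
  vapply(0:max_lag, function(k) sum(xc[1:(n - k)] * xc[(1 + k):n]) / n,
         numeric(1))
}

new_correlogram <- function(lag, value, n, kind) {
  structure(data.frame(lag = lag, value = value,
                       bound = 1.96 / sqrt(n), kind = kind),
            class = c("correlogram", "data.frame"), n = n)
}

#' Sample autocorrelation function
#'
#' Standard correlogram with the biased (1/n) denominator,
#' \eqn{r_k = \sum (x_t-\bar x)(x_{t+k}-\bar x) / \sum (x_t-\bar x)^2},
#' with the large-sample white-noise 95\% bound \eqn{\pm 1.96/\sqrt n}
#' attached at every lag.
#'
#' @param values numeric series (no NA).
#' @param max_lag largest lag, \code{1 <= max_lag < n}.
#' @return a \code{correlogram} data.frame: \code{lag, value, bound, kind}.
#' @export
acf_corr <- function(values, max_lag) {
  x <- as.numeric(values)
  if (anyNA(x)) stop("values must not contain NA", call. = FALSE)
  n <- length(x)
  if (max_lag < 1 || max_lag >= n)
    stop("need n > max_lag >= 1", call. = FALSE)
  g <- sample_acov(x, max_lag)
  if (g[1] <= 0) stop("constant series: autocorrelation undefined", call. = FALSE)
  new_correlogram(1:max_lag, g[-1] / g[1], n, "ACF")
}

# Durbin-Levinson recursion: sample PACF from an autocorrelation sequence
# rho = (rho_1, ..., rho_L); returns partial autocorrelations at lags 1..L
durbin_levinson <- function(rho) {
  L <- length(rho)
  pacf <- numeric(L)
  phi_prev <- numeric(0)
  for (k in 1:L) {
    if (k == 1) {
      a <- rho[1]
    } else {
      num <- rho[k] - sum(phi_prev * rho[(k - 1):1])
      den <- 1 - sum(phi_prev * rho[1:(k - 1)])
      a <- num / den
    }
    pacf[k] <- a
    phi <- c(phi_prev - a * rev(phi_prev), a)
    phi_prev <- phi
  }
  pacf
}

#' Sample partial autocorrelation function
#'
#' PACF via the Durbin-Levinson recursion applied to the sample ACF
#' (biased denominator). The lag-1 value equals the lag-1 ACF.
#'
#' @inheritParams acf_corr
#' @return a \code{correlogram} data.frame with \code{kind = "PACF"}.
#' @export
pacf_corr <- function(values, max_lag) {
  a <- acf_corr(values, max_lag)
  new_correlogram(1:max_lag, durbin_levinson(a$value), attr(a, "n"), "PACF")
}

#' Partial rate correlation function (PRCF)
#'
#' Order diagnostic for density-dependent feedback: a PACF of the detrended
#' rate of change whose lag-1 entry is replaced by the Pearson correlation
#' between the detrended rates and the lagged log abundance
#' \eqn{MFT_{t-1}}. Lags >= 2 are identical to the PACF of the detrended
#' rates.
#'
#' @param detrended_rate detrended \eqn{R_t} values.
#' @param mft_lag1 \eqn{MFT_{t-1}} aligned to the rates.
#' @param max_lag largest lag.
#' @return a \code{correlogram} data.frame with \code{kind = "PRCF"}.
#' @export
prcf <- function(detrended_rate, mft_lag1, max_lag) {
  if (length(detrended_rate) != length(mft_lag1))
    stop("detrended_rate and mft_lag1 must be aligned (same length)",
         call. = FALSE)
  if (sd(mft_lag1) == 0)
    stop("mft_lag1 is constant: lag-1 rate correlation undefined",
         call. = FALSE)
  p <- pacf_corr(detrended_rate, max_lag)
  p$value[1] <- cor(detrended_rate, mft_lag1)
  p$kind <- "PRCF"
  p
}

#' Diagnose a population series
#'
#' Convenience wrapper running the full order-diagnostic chain on the longest
#' contiguous stretch of rates: trend test, detrending, ACF and PRCF.
#'
#' @param series a \code{population_series}.
#' @param max_lag largest lag (default \code{min(15, n/2)} rounded).
#' @param all_stretches analyze every contiguous stretch (list) instead of
#'   the longest one.
#' @return list with \code{rate, trend, detrended, acf, prcf} (or a list of
#'   such, one per stretch).
#' @export
diagnose_series <- function(series, max_lag = NULL, all_stretches = FALSE) {
  rate <- rate_of_change(series)
  one <- function(rt) {
    n <- nrow(rt)
    L <- if (is.null(max_lag)) max(1L, min(15L, floor(n / 2))) else max_lag
    tr <- linear_trend_test(rt$r, rt$time)
    dt <- detrend_rate(rt, tr)
    list(rate = rt, trend = tr, detrended = dt,
         acf = acf_corr(dt, L), prcf = prcf(dt, rt$mft_lag, L))
  }
  if (all_stretches) {
    brk <- cumsum(c(0, diff(rate$time) != 1L))
    lapply(split(rate, brk), function(rt) {
      if (nrow(rt) >= 6) one(`class<-`(rt, class(rate))) else NULL
    })
  } else {
    one(longest_stretch(rate))
  }
}

#' Variance inflation factors
#'
#' Collinearity screen: for each column of the design,
#' \eqn{VIF_j = 1/(1-R_j^2)} where \eqn{R_j^2} comes from regressing column
#' \eqn{j} on the remaining columns (with intercept). A perfectly collinear
#' column reports \code{Inf}.
#'
#' @param x numeric matrix or data.frame of design columns (>= 2 columns).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 columns", call. = FALSE)
  if (nrow(x) <= ncol(x)) stop("need more rows than columns", call. = FALSE)
  vapply(seq_len(ncol(x)), function(j) {
    fit <- lm(x[, j] ~ x[, -j, drop = FALSE])
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> setNames(colnames(x))
}

#' Write a correlogram to CSV
#'
#' @param x a \code{correlogram}.
#' @param path output CSV path.
#' @export
write_correlogram <- function(x, path) {
  stopifnot(inherits(x, "correlogram"))
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
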