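# ---- simulation-extrapolation (SIMEX) for measurement error ----------------
# Sampling error in the trap-derived log abundance attenuates the estimated
# density-dependence coefficient. SIMEX quantifies and corrects this: refit
# the linear model with progressively inflated noise on the error-prone
# predictor (variance lambda * sigma_u^2), average over B replicates per
# lambda, fit a quadratic in lambda through the means (and the naive fit at
# lambda = 0), and read off the extrapolation at lambda = -1.

#' Naive linear fit of the rate-of-change model
#'
#' OLS of the basic model, ignoring measurement error in the predictors;
#' the SIMEX starting point.
#'
#' @param data a \code{rate_series} or data.frame (complete cases used).
#' @param formula model formula (default the basic rate model).
#' @return an \code{lm} fit.
#' @export
naive_fit <- function(data, formula = r ~ mft_lag + nlst + naoi + fruit) {
  d <- as.data.frame(data)
  d <- d[complete.cases(d[, all.vars(formula)]), , drop = FALSE]
  lm(formula, data = d)
}

#' Pooled measurement-error SD of the log abundance index
#'
#' Default estimator of \code{sigma_u} for SIMEX when per-trap counts are
#' available: the pooled within-month standard error of per-trap
#' \eqn{\ln(catch + 1)} — the within-month between-trap SD divided by
#' \eqn{\sqrt{n_{traps}}}, pooled across months.
#'
#' @param catch matrix-like of per-trap catches (rows = months, columns =
#'   traps) or a data.frame with columns \code{month} and \code{catch} (one
#'   row per trap).
#' @return estimated measurement-error SD on the MFT (log) scale.
#' @export
estimate_sigma_u <- function(catch) {
  if (is.data.frame(catch) && all(c("month", "catch") %in% names(catch))) {
    groups <- split(log(catch$catch + 1), catch$month)
  } else {
    m <- as.matrix(catch)
    groups <- split(log(m + 1), row(m))
  }
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) == 0)
    stop("need at least one month with >= 2 traps", call. = FALSE)
  # pooled within-month variance of the per-trap log counts, scaled to the
  # SE of the month mean
  ss <- vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))
  df <- vapply(groups, function(g) length(g) - 1, numeric(1))
  nbar <- mean(lengths(groups))
  sqrt(sum(ss) / sum(df) / nbar)
}

# linear weights of the quadratic extrapolation to lambda = -1:
# value(-1) = sum_j c_j * mean_j over the lambda grid (0 included)
extrapolation_weights <- function(lambdas, extrapolant = c("quadratic", "linear")) {
  extrapolant <- match.arg(extrapolant)
  # a quadratic needs three support points; degrade gracefully on tiny grids
  if (extrapolant == "quadratic" && length(lambdas) < 3)
    extrapolant <- "linear"
  Lam <- if (extrapolant == "quadratic") cbind(1, lambdas, lambdas^2)
  else cbind(1, lambdas)
  v <- if (extrapolant == "quadratic") c(1, -1, 1) else c(1, -1)
  drop(v %*% solve(crossprod(Lam), t(Lam)))
}

#' SIMEX estimate of the rate-of-change model
#'
#' @param data a \code{rate_series} or data.frame.
#' @param sigma_u measurement-error SD of the error-prone predictor on its
#'   own (log) scale; see \code{\link{estimate_sigma_u}}.
#' @param formula model formula.
#' @param simex_var name of the error-prone predictor (default
#'   \code{"mft_lag"}).
#' @param lambdas grid of added-error variance multipliers, all > 0
#'   (default \code{c(0.5, 1, 1.5, 2, 2.5, 3)}).
#' @param B pseudo-replicates per lambda (default 100).
#' @param extrapolant \code{"quadratic"} (default) or \code{"linear"}.
#' @param seed RNG seed for the pseudo-errors.
#' @return object of class \code{simex_result}: \code{naive} coefficients
#'   and their model SEs, \code{lambda_means} (per-lambda coefficient
#'   means, lambda = 0 row first), \code{estimate} (extrapolated
#'   coefficients at lambda = -1), per-coefficient \code{se_asymptotic} and
#'   \code{se_jackknife}, p-values on t(n - k) df, and the replicate store.
#' @export
simex_fit <- function(data, sigma_u, formula = r ~ mft_lag + nlst + naoi + fruit,
                      simex_var = "mft_lag",
                      lambdas = c(0.5, 1, 1.5, 2, 2.5, 3), B = 100,
                      extrapolant = c("quadratic", "linear"), seed = NULL) {
  extrapolant <- match.arg(extrapolant)
  if (any(lambdas <= 0)) stop("all lambdas must be > 0", call. = FALSE)
  if (sigma_u < 0) stop("sigma_u must be >= 0", call. = FALSE)
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  d <- as.data.frame(data)
  d <- d[complete.cases(d[, all.vars(formula)]), , drop = FALSE]
  nv <- naive_fit(d, formula)
  X0 <- model.matrix(nv)
  y <- stats::model.response(stats::model.frame(nv))
  n <- nrow(X0); kk <- ncol(X0)
  cn <- colnames(X0)
  if (!simex_var %in% cn)
    stop("simex_var '", simex_var, "' is not a model column", call. = FALSE)
  naive_coef <- coef(nv)
  naive_se <- sqrt(diag(vcov(nv)))
  naive_if <- influence_ols(X0, y, naive_coef)

  if (sigma_u == 0) {
    # degenerate case: no measurement error, SIMEX reduces to the naive fit
    res <- structure(list(
      naive = naive_coef, naive_se = naive_se, estimate = naive_coef,
      se_asymptotic = naive_se, se_jackknife = naive_se,
      p_asymptotic = 2 * pt(-abs(naive_coef / naive_se), n - kk),
      p_jackknife = 2 * pt(-abs(naive_coef / naive_se), n - kk),
      lambdas = c(0, lambdas),
      lambda_means = matrix(rep(naive_coef, length(lambdas) + 1),
                            ncol = kk, byrow = TRUE,
                            dimnames = list(NULL, cn)),
      sigma_u = 0, B = B, extrapolant = extrapolant, n = n, k = kk,
      replicates = NULL, simex_var = simex_var), class = "simex_result")
    return(res)
  }

  if (!is.null(seed)) set.seed(seed)
  L <- length(lambdas)
  est <- array(NA_real_, c(L, B, kk), dimnames = list(NULL, NULL, cn))
  modvar <- array(NA_real_, c(L, B, kk), dimnames = list(NULL, NULL, cn))
  if_sum <- array(0, c(L, n, kk))   # per-lambda sum over b of influence values
  jvar <- which(cn == simex_var)
  for (b in seq_len(B)) {
    for (l in seq_len(L)) {
      Xl <- X0
      Xl[, jvar] <- X0[, jvar] + rnorm(n, sd = sqrt(lambdas[l]) * sigma_u)
      qrX <- qr(Xl)
      bet <- qr.coef(qrX, y)
      res_l <- y - Xl %*% bet
      s2 <- sum(res_l^2) / (n - kk)
      XtXinv <- chol2inv(qr.R(qrX))
      est[l, b, ] <- bet
      modvar[l, b, ] <- s2 * diag(XtXinv)
      if_sum[l, , ] <- if_sum[l, , ] + influence_ols(Xl, y, bet)
    }
  }
  means <- apply(est, c(1, 3), mean)                   # L x k
  between <- apply(est, c(1, 3), var)                  # between-replicate
  if (B == 1) between[] <- 0
  vmodel <- apply(modvar, c(1, 3), mean)

  lam_all <- c(0, lambdas)
  w <- extrapolation_weights(lam_all, extrapolant)
  mean_all <- rbind(naive_coef, means)
  estimate <- drop(w %*% mean_all)
  names(estimate) <- cn

  # jackknife (difference) variance: extrapolate the per-lambda data-only
  # variance component, model-based variance minus the delete-one
  # between-replicate variance of the added noise
  between_all <- rbind(0, between)
  vmodel_all <- rbind(naive_se^2, vmodel)
  var_jack <- drop(w %*% (vmodel_all - between_all))
  se_jack <- sqrt(pmax(var_jack, 0))

  # sandwich/delta-method variance: the extrapolated estimator is a linear
  # combination (weights w) of per-lambda mean estimates, whose joint
  # sampling covariance over the data is estimated from the per-observation
  # influence values averaged over replicates
  se_asym <- numeric(kk)
  for (j in seq_len(kk)) {
    mi <- matrix(if_sum[, , j, drop = FALSE], nrow = L) # L x n
    A <- cbind(naive_if[, j], t(mi) / B)                # n x (L+1)
    S <- crossprod(A)
    se_asym[j] <- sqrt(max(drop(t(w) %*% S %*% w), 0))
  }
  names(se_asym) <- names(se_jack) <- cn

  structure(list(
    naive = naive_coef, naive_se = naive_se, estimate = estimate,
    se_asymptotic = se_asym, se_jackknife = se_jack,
    p_asymptotic = 2 * pt(-abs(estimate / se_asym), n - kk),
    p_jackknife = 2 * pt(-abs(estimate / se_jack), n - kk),
    lambdas = lam_all, lambda_means = mean_all, sigma_u = sigma_u, B = B,
    extrapolant = extrapolant, n = n, k = kk,
    replicates = est, simex_var = simex_var), class = "simex_result")
}

# per-observation OLS influence values (X'X)^-1 x_i e_i, returned n x k
influence_ols <- function(X, y, beta) {
  e <- drop(y - X %*% beta)
  (e * X) %*% chol2inv(chol(crossprod(X)))
}

#' Standard errors of a SIMEX estimate
#'
#' @param result a \code{simex_result}.
#' @param method \code{"asymptotic"} (sandwich/delta-method on the
#'   extrapolation) or \code{"jackknife"} (difference method over the
#'   replicate store).
#' @return named vector of standard errors.
#' @export
simex_variance <- function(result, method = c("asymptotic", "jackknife")) {
  method <- match.arg(method)
  if (method == "jackknife" && !is.null(result$replicates) && result$B < 2)
    stop("jackknife variance needs B >= 2 replicates", call. = FALSE)
  if (method == "asymptotic") result$se_asymptotic else result$se_jackknife
}

#' @export
print.simex_result <- function(x, digits = 4, ...) {
  cat(sprintf("SIMEX (%s extrapolant, sigma_u = %.4g, B = %d, n = %d)\n",
              x$extrapolant, x$sigma_u, x$B, x$n))
  tab <- cbind(naive = x$naive, simex = x$estimate,
               se_asymptotic = x$se_asymptotic,
               se_jackknife = x$se_jackknife, p = x$p_asymptotic)
  print(round(tab, digits))
  invisible(x)
}

#' @rdname fit_to_table
#' @param x a \code{simex_result}.
#' @export
simex_to_json <- function(x) {
  jsonlite::toJSON(list(
    sigma_u = x$sigma_u, B = x$B, extrapolant = x$extrapolant,
    lambdas = x$lambdas,
    lambda_means = as.data.frame(x$lambda_means),
    naive = as.list(x$naive), estimate = as.list(x$estimate),
    se_asymptotic = as.list(x$se_asymptotic),
    se_jackknife = as.list(x$se_jackknife)), auto_unbox = TRUE, digits = NA)
}
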