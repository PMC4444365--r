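# ---- generalized least squares with ARMA errors ----------------------------
# The engine behind the rate-of-change models: y = X beta + e with
# e ~ N(0, sigma^2 * D R D), R the ARMA(p,q) correlation at the true integer
# month separations and D a diagonal weight built from stratified and/or
# covariate-proportional variance structures. beta and sigma^2 are profiled
# out; the ARMA parameters and stratum variance ratios are maximized
# numerically in an unconstrained (partial-autocorrelation / log) transform.

#' Variance structure for the GLS model
#'
#' Describes how the residual standard deviation varies across observations:
#' \itemize{
#'   \item \code{strata}: factor column names; each factor contributes a free
#'     multiplicative SD ratio per level (reference level fixed at 1; several
#'     factors combine multiplicatively).
#'   \item \code{covariate}: a strictly positive column name \code{v};
#'     contributes a fixed (parameter-free) weight \eqn{\sqrt{v_i}}, i.e.
#'     variance proportional to the covariate. \code{offset} is added first
#'     for covariates that can be non-positive (e.g. temperatures below 0).
#' }
#' Both may be combined (their weights multiply).
#'
#' @param strata character vector of factor column names (or NULL).
#' @param covariate single column name (or NULL).
#' @param offset value added to the covariate before weighting.
#' @return object of class \code{var_structure}.
#' @export
variance_structure <- function(strata = NULL, covariate = NULL, offset = 0) {
  structure(list(strata = strata, covariate = covariate, offset = offset),
            class = "var_structure")
}

var_label <- function(v) {
  parts <- c(if (!is.null(v$covariate)) paste0("prop(", v$covariate, ")"),
             if (!is.null(v$strata)) paste0("strata(", paste(v$strata, collapse = ":"), ")"))
  if (length(parts) == 0) "none" else paste(parts, collapse = "*")
}

#' GLS model specification
#'
#' @param fixed model formula for the fixed effects (default the basic
#'   rate-of-change model: lagged log abundance plus temperature, climate
#'   index and fruit availability).
#' @param arma integer vector \code{c(p, q)} with \code{p, q <= 2} by
#'   convention (\code{p + q <= 4}).
#' @param variance a \code{\link{variance_structure}}.
#' @param method \code{"ML"} or \code{"REML"}.
#' @return object of class \code{gls_spec}.
#' @export
gls_spec <- function(fixed = r ~ mft_lag + nlst + naoi + fruit,
                     arma = c(0, 0), variance = variance_structure(),
                     method = c("ML", "REML")) {
  arma <- as.integer(arma)
  stopifnot(length(arma) == 2, all(arma >= 0))
  if (sum(arma) > 4) stop("p + q must be <= 4", call. = FALSE)
  structure(list(fixed = fixed, arma = arma, variance = variance,
                 method = match.arg(method)),
            class = "gls_spec")
}

spec_label <- function(spec) {
  sprintf("ARMA(%d,%d) / %s", spec$arma[1], spec$arma[2],
          var_label(spec$variance))
}

#' @export
print.gls_spec <- function(x, ...) {
  cat("<gls_spec>", deparse(x$fixed), "|", spec_label(x), "|", x$method, "\n")
  invisible(x)
}

# diagonal SD weights from the variance structure; ratios is a named list
# (one named vector of per-level SD ratios per stratum factor)
variance_weights <- function(variance, data, ratios = NULL) {
  n <- nrow(data)
  w <- rep(1, n)
  if (!is.null(variance$covariate)) {
    v <- data[[variance$covariate]] + variance$offset
    if (is.null(v)) stop("variance covariate not found in data", call. = FALSE)
    if (any(is.na(v)) || any(v <= 0))
      stop("variance covariate must be strictly positive (use offset)",
           call. = FALSE)
    w <- w * sqrt(v)
  }
  for (f in variance$strata) {
    lev <- data[[f]]
    if (is.null(lev)) stop("stratum factor '", f, "' not found", call. = FALSE)
    lev <- droplevels(as.factor(lev))
    rat <- ratios[[f]]
    if (is.null(rat)) rat <- setNames(rep(1, nlevels(lev)), levels(lev))
    w <- w * unname(rat[as.character(lev)])
  }
  w
}

# number of free variance-ratio parameters per stratum factor
ratio_param_counts <- function(variance, data) {
  counts <- integer(0)
  for (f in variance$strata) {
    lev <- droplevels(as.factor(data[[f]]))
    counts <- c(counts, setNames(nlevels(lev) - 1L, f))
  }
  counts
}

#' Build the residual covariance factorization
#'
#' Returns the unit-scale covariance \eqn{\Sigma_0 = D R D}: the ARMA
#' correlation matrix \code{R} evaluated at the true integer month
#' separations between observations (so rows separated by a sampling gap get
#' the correlation of their actual distance) and the diagonal SD weights
#' \code{w} of the variance structure.
#'
#' @param spec a \code{gls_spec}.
#' @param data data.frame with the model columns; integer time positions are
#'   taken from a \code{time} column when present, otherwise row order.
#' @param phi,theta ARMA parameters.
#' @param ratios named list of per-factor SD ratio vectors (reference level
#'   1); defaults to all 1.
#' @param gap_handling \code{"true-separation"} (default) or
#'   \code{"adjacent"} (rows treated as consecutive regardless of gaps).
#' @return list with correlation matrix \code{R}, weights \code{w}, and
#'   \code{sigma0 = diag(w) R diag(w)}.
#' @export
build_sigma <- function(spec, data, phi = numeric(0), theta = numeric(0),
                        ratios = NULL,
                        gap_handling = c("true-separation", "adjacent")) {
  gap_handling <- match.arg(gap_handling)
  n <- nrow(data)
  tt <- if (gap_handling == "true-separation" && !is.null(data$time))
    as.integer(data$time) else seq_len(n)
  sep <- abs(outer(tt, tt, "-"))
  if (length(phi) == 0 && length(theta) == 0) {
    R <- diag(n)
  } else {
    rho <- arma_acf(phi, theta, max(sep))
    R <- matrix(rho[sep + 1L], n, n)
  }
  w <- variance_weights(spec$variance, data, ratios)
  list(R = R, w = w, sigma0 = R * outer(w, w))
}

# profiled log-likelihood core; returns the pieces fit_gls needs
gls_profile <- function(y, X, sigma0, method) {
  n <- length(y); k <- ncol(X)
  L <- tryCatch(chol(sigma0), error = function(e)
    stop("covariance not positive definite at these parameters", call. = FALSE))
  logdet <- 2 * sum(log(diag(L)))
  ys <- backsolve(L, y, transpose = TRUE)
  Xs <- backsolve(L, X, transpose = TRUE)
  qrX <- qr(Xs)
  if (qrX$rank < k) stop("singular design (rank-deficient X)", call. = FALSE)
  beta <- qr.coef(qrX, ys)
  res <- ys - Xs %*% beta
  rss <- sum(res^2)
  XtX <- crossprod(qr.R(qrX))           # X' Sigma0^-1 X
  if (method == "ML") {
    sigma2 <- max(rss / n, 1e-300)
    ll <- -n / 2 * log(2 * pi) - logdet / 2 - n / 2 * log(sigma2) - n / 2
  } else {
    sigma2 <- max(rss / (n - k), 1e-300)
    ldXtX <- as.numeric(determinant(XtX, logarithm = TRUE)$modulus)
    ll <- -(n - k) / 2 * log(2 * pi) - logdet / 2 - ldXtX / 2 -
      (n - k) / 2 * log(sigma2) - (n - k) / 2
  }
  list(loglik = ll, beta = drop(beta), sigma2 = sigma2, XtX = XtX,
       wres = drop(res), L = L)
}

prepare_model_frame <- function(spec, data) {
  vars <- unique(c(all.vars(spec$fixed), spec$variance$strata,
                   spec$variance$covariate,
                   if (!is.null(data$time)) "time"))
  vars <- intersect(vars, names(data))
  d <- data[, vars, drop = FALSE]
  ok <- complete.cases(d)
  d <- d[ok, , drop = FALSE]
  X <- model.matrix(spec$fixed[-2], d)
  y <- eval(spec$fixed[[2]], d)
  list(data = d, X = X, y = y, kept = which(ok))
}

#' Profiled GLS log-likelihood at given correlation/variance parameters
#'
#' Evaluates the (RE)ML log-likelihood of the model in \code{spec} with the
#' regression coefficients and the residual scale profiled out analytically.
#'
#' @inheritParams build_sigma
#' @param method override of the spec's estimation method.
#' @return scalar log-likelihood.
#' @export
gls_loglik <- function(spec, data, phi = numeric(0), theta = numeric(0),
                       ratios = NULL, method = spec$method,
                       gap_handling = "true-separation") {
  mf <- prepare_model_frame(spec, data)
  sg <- build_sigma(spec, mf$data, phi, theta, ratios, gap_handling)
  gls_profile(mf$y, mf$X, sg$sigma0, method)$loglik
}

#' Control parameters for the GLS optimizer
#'
#' @param restarts number of random restarts of the quasi-Newton search in
#'   addition to the zero start.
#' @param seed seed for the restart jitter.
#' @param reltol relative convergence tolerance on the log-likelihood.
#' @param gap_handling see \code{\link{build_sigma}}.
#' @export
gls_control <- function(restarts = 3, seed = 1L, reltol = 1e-10,
                        gap_handling = "true-separation") {
  list(restarts = restarts, seed = seed, reltol = reltol,
       gap_handling = gap_handling)
}

#' Fit a GLS model with ARMA errors and variance structure
#'
#' Maximizes the profiled (RE)ML likelihood over the ARMA parameters
#' (optimized through a partial-autocorrelation transform that enforces
#' stationarity and invertibility) and the log variance ratios. Coefficient
#' standard errors come from \eqn{\hat\sigma^2 (X'\hat\Sigma_0^{-1}X)^{-1}}
#' and p-values from the t distribution on \eqn{n - k} df.
#'
#' @param spec a \code{\link{gls_spec}}.
#' @param data a \code{rate_series} or data.frame holding the model columns.
#' @param control a \code{\link{gls_control}} list.
#' @return object of class \code{gls_fit}: coefficient table, \code{phi},
#'   \code{theta}, per-stratum SD \code{ratios}, \code{sigma}, \code{logLik},
#'   \code{BIC} (with \code{n_par} counting beta, sigma, phi, theta and
#'   ratios), normalized residuals, and a \code{converged} flag
#'   (non-convergence is flagged, not an error).
#' @export
fit_gls <- function(spec, data, control = gls_control()) {
  mf <- prepare_model_frame(spec, data)
  n <- length(mf$y); k <- ncol(mf$X)
  p <- spec$arma[1]; q <- spec$arma[2]
  rc <- ratio_param_counts(spec$variance, mf$data)
  npar_corr <- p + q + sum(rc)
  if (n <= k + npar_corr)
    stop("more parameters than observations", call. = FALSE)

  unpack <- function(z) {
    phi <- if (p > 0) uncons_to_coef(z[seq_len(p)]) else numeric(0)
    theta <- if (q > 0) uncons_to_coef(z[p + seq_len(q)]) else numeric(0)
    ratios <- NULL
    off <- p + q
    for (f in names(rc)) {
      lev <- levels(droplevels(as.factor(mf$data[[f]])))
      ratios[[f]] <- setNames(c(1, exp(z[off + seq_len(rc[[f]])])), lev)
      off <- off + rc[[f]]
    }
    list(phi = phi, theta = theta, ratios = ratios)
  }
  objective <- function(z) {
    ll <- tryCatch({
      pr <- unpack(z)
      sg <- build_sigma(spec, mf$data, pr$phi, pr$theta, pr$ratios,
                        control$gap_handling)
      gls_profile(mf$y, mf$X, sg$sigma0, spec$method)$loglik
    }, error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }

  converged <- TRUE
  message_txt <- NULL
  if (npar_corr == 0) {
    z_hat <- numeric(0)
  } else {
    # starts: zero, a moment-based init (partial autocorrelations of the OLS
    # residuals for the AR block), and seeded jitters
    starts <- list(rep(0, npar_corr))
    if (p > 0) {
      z_mom <- rep(0, npar_corr)
      mom <- tryCatch({
        ols_res <- qr.resid(qr(mf$X), mf$y)
        pc <- pacf_corr(ols_res, p)$value
        atanh(pmin(pmax(pc, -0.9), 0.9))
      }, error = function(e) NULL)
      if (!is.null(mom) && all(is.finite(mom))) {
        z_mom[seq_len(p)] <- mom
        starts[[length(starts) + 1]] <- z_mom
      }
    }
    if (control$restarts > 0) {
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      set.seed(control$seed)
      for (i in seq_len(control$restarts))
        starts[[length(starts) + 1]] <- rnorm(npar_corr, sd = 0.6)
      if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    }
    best <- NULL
    for (s in starts) {
      o <- tryCatch(
        optim(s, objective, method = "L-BFGS-B", lower = -4, upper = 4,
              control = list(factr = control$reltol / .Machine$double.eps,
                             maxit = 500)),
        error = function(e) NULL)
      if (is.null(o)) next
      if (is.null(best) || o$value < best$value) best <- o
    }
    if (is.null(best)) {
      converged <- FALSE
      message_txt <- "all optimizer starts failed"
      z_hat <- rep(0, npar_corr)
    } else {
      z_hat <- best$par
      if (best$convergence != 0) {
        converged <- FALSE
        message_txt <- paste("optim convergence code", best$convergence)
      }
    }
  }

  pr <- unpack(z_hat)
  sg <- build_sigma(spec, mf$data, pr$phi, pr$theta, pr$ratios,
                    control$gap_handling)
  prof <- gls_profile(mf$y, mf$X, sg$sigma0, spec$method)
  vcov_beta <- prof$sigma2 * solve(prof$XtX)
  se <- sqrt(diag(vcov_beta))
  tval <- prof$beta / se
  pval <- 2 * pt(-abs(tval), df = n - k)
  coefs <- data.frame(term = colnames(mf$X), estimate = unname(prof$beta),
                      se = unname(se), t = unname(tval), p = unname(pval),
                      stringsAsFactors = FALSE)
  n_par <- k + 1L + npar_corr
  ll <- prof$loglik
  fit <- structure(list(
    spec = spec, coefficients = coefs, phi = pr$phi, theta = pr$theta,
    ratios = pr$ratios, sigma = sqrt(prof$sigma2), logLik = ll,
    BIC = -2 * ll + n_par * log(n), n = n, k = k, n_par = n_par,
    vcov = vcov_beta, method = spec$method,
    residuals = drop(mf$y - mf$X %*% prof$beta),
    normalized_residuals = prof$wres / sqrt(prof$sigma2),
    fitted = drop(mf$X %*% prof$beta), rows_used = mf$kept,
    converged = converged, message = message_txt), class = "gls_fit")
  fit
}

#' @export
print.gls_fit <- function(x, digits = 4, ...) {
  cat(sprintf("GLS fit (%s), %s\n", x$method, spec_label(x$spec)))
  cat(sprintf("  n = %d, logLik = %.3f, BIC = %.3f (%d parameters)%s\n",
              x$n, x$logLik, x$BIC, x$n_par,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  printCoefmat(cbind(Estimate = x$coefficients$estimate,
                     `Std.Error` = x$coefficients$se,
                     `t value` = x$coefficients$t,
                     `p value` = x$coefficients$p),
               digits = digits, P.values = TRUE, has.Pvalue = TRUE)
  if (length(x$phi)) cat("  phi:", paste(round(x$phi, 3), collapse = ", "), "\n")
  if (length(x$theta)) cat("  theta:", paste(round(x$theta, 3), collapse = ", "), "\n")
  for (f in names(x$ratios))
    cat(sprintf("  SD ratios (%s): %s\n", f,
                paste(names(x$ratios[[f]]), round(x$ratios[[f]], 3),
                      sep = "=", collapse = ", ")))
  cat(sprintf("  sigma = %.4f\n", x$sigma))
  invisible(x)
}

#' @export
coef.gls_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
vcov.gls_fit <- function(object, ...) object$vcov

#' @export
logLik.gls_fit <- function(object, ...) {
  structure(object$logLik, df = object$n_par, class = "logLik")
}

#' Serialize a fitted model
#'
#' \code{fit_to_table} gives a one-row-per-term CSV-ready summary (term,
#' estimate, SE, p, plus the ARMA and variance structure, logLik and BIC);
#' \code{fit_to_json} the same as a JSON string.
#'
#' @param fit a \code{gls_fit}.
#' @return data.frame / JSON string.
#' @export
fit_to_table <- function(fit) {
  cbind(fit$coefficients,
        arma_p = fit$spec$arma[1], arma_q = fit$spec$arma[2],
        phi = paste(round(fit$phi, 4), collapse = ";"),
        theta = paste(round(fit$theta, 4), collapse = ";"),
        variance = var_label(fit$spec$variance), method = fit$method,
        sigma = fit$sigma, logLik = fit$logLik, BIC = fit$BIC, n = fit$n)
}

#' @rdname fit_to_table
#' @export
fit_to_json <- function(fit) {
  jsonlite::toJSON(list(
    spec = list(fixed = deparse(fit$spec$fixed), arma = fit$spec$arma,
                variance = var_label(fit$spec$variance),
                method = fit$method),
    coefficients = fit$coefficients, phi = fit$phi, theta = fit$theta,
    ratios = fit$ratios, sigma = fit$sigma, logLik = fit$logLik,
    BIC = fit$BIC, n = fit$n, n_par = fit$n_par,
    converged = fit$converged), auto_unbox = TRUE, digits = NA)
}
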