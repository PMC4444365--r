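# ---- model selection over correlation and variance structures --------------

#' Default variance-structure candidates
#'
#' The six structures explored by default: homoscedastic, per-season strata,
#' per-year strata, season and year strata combined, variance proportional
#' to nLST, and the full combination of the nLST weight with both stratum
#' factors.
#'
#' @param nlst_offset offset for the nLST weight (sites with sub-zero
#'   temperatures need one).
#' @return named list of \code{\link{variance_structure}} objects.
#' @export
default_variance_set <- function(nlst_offset = 0) {
  list(none = variance_structure(),
       season = variance_structure(strata = "season"),
       year = variance_structure(strata = "year"),
       season_year = variance_structure(strata = c("season", "year")),
       nlst = variance_structure(covariate = "nlst", offset = nlst_offset),
       nlst_season_year = variance_structure(strata = c("season", "year"),
                                             covariate = "nlst",
                                             offset = nlst_offset))
}

#' Enumerate candidate model specifications
#'
#' Cross product of ARMA orders up to \code{arma_max} with the supplied
#' variance structures, all sharing the base fixed-effects formula.
#' Duplicates (same order and structure) collapse. The null candidate
#' ARMA(0,0)/homoscedastic is always included.
#'
#' @param base_spec a \code{\link{gls_spec}} providing the fixed formula and
#'   estimation method.
#' @param arma_max integer \code{c(p_max, q_max)} (default \code{c(2, 2)}).
#' @param variance_set list of \code{\link{variance_structure}}s (default
#'   \code{\link{default_variance_set}()}).
#' @return list of \code{gls_spec} objects.
#' @export
enumerate_candidates <- function(base_spec = gls_spec(),
                                 arma_max = c(2, 2),
                                 variance_set = default_variance_set()) {
  if (length(variance_set) == 0 || any(arma_max < 0))
    stop("empty candidate grid", call. = FALSE)
  orders <- expand.grid(p = 0:arma_max[1], q = 0:arma_max[2])
  orders <- orders[order(orders$p + orders$q, orders$p), ]
  out <- list()
  seen <- character(0)
  for (i in seq_len(nrow(orders))) {
    for (v in variance_set) {
      key <- paste(orders$p[i], orders$q[i], var_label(v))
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1]] <- gls_spec(base_spec$fixed,
                                         c(orders$p[i], orders$q[i]),
                                         v, base_spec$method)
    }
  }
  if (!any(vapply(out, function(s)
    all(s$arma == 0) && var_label(s$variance) == "none", logical(1))))
    stop("candidate set must contain the null ARMA(0,0)/no-structure spec",
         call. = FALSE)
  out
}

# Ljung-Box white-noise verdict on normalized residuals, plus the plain
# ACF bound-exceedance fraction for reporting
white_noise_check <- function(res, lags = NULL, alpha = 0.05) {
  n <- length(res)
  if (is.null(lags)) lags <- max(1L, min(10L, floor(n / 5)))
  bt <- Box.test(res, lag = lags, type = "Ljung-Box")
  cg <- acf_corr(res, lags)
  list(pass = bt$p.value > alpha, p_value = unname(bt$p.value), lags = lags,
       exceedance = mean(abs(cg$value) > cg$bound[1]))
}

#' Select the best GLS model by BIC with a parsimony tie-break
#'
#' Fits every candidate by ML, ranks by BIC, and among candidates whose BIC
#' lies within \code{delta} of the minimum picks the one with the fewest
#' parameters (lowest BIC breaking remaining ties). The leader's normalized
#' residuals get a Ljung-Box white-noise check, and the winner is refitted
#' by REML. Candidates that fail to fit are excluded with a logged reason.
#'
#' @param data a \code{rate_series} or data.frame.
#' @param candidates list of \code{gls_spec}s (default
#'   \code{\link{enumerate_candidates}()}).
#' @param delta BIC window treated as "no significant difference" (default 2).
#' @param control a \code{\link{gls_control}}.
#' @param refit_reml refit the chosen model by REML (default TRUE).
#' @return object of class \code{selection_result}: ranked \code{table}
#'   (label, p, q, variance, n_par, logLik, BIC, delta_bic, converged),
#'   \code{chosen} spec, \code{fit_ml}, \code{fit_reml}, \code{white_noise}
#'   verdict, \code{lrt} table of nested likelihood-ratio comparisons
#'   against the chosen model, and \code{failures}.
#' @export
select_model <- function(data, candidates = enumerate_candidates(),
                         delta = 2, control = gls_control(restarts = 1),
                         refit_reml = TRUE) {
  fits <- vector("list", length(candidates))
  failures <- character(0)
  for (i in seq_along(candidates)) {
    sp <- candidates[[i]]
    sp$method <- "ML"
    f <- tryCatch(fit_gls(sp, data, control), error = function(e) e)
    if (inherits(f, "error")) {
      failures <- c(failures, paste0(spec_label(sp), ": ", conditionMessage(f)))
      fits[[i]] <- NULL
    } else fits[[i]] <- f
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("all candidates failed to fit:\n  ",
         paste(failures, collapse = "\n  "), call. = FALSE)
  fits <- fits[ok]
  tab <- do.call(rbind, lapply(fits, function(f) data.frame(
    label = spec_label(f$spec), p = f$spec$arma[1], q = f$spec$arma[2],
    variance = var_label(f$spec$variance), n_par = f$n_par,
    logLik = f$logLik, BIC = f$BIC, converged = f$converged,
    stringsAsFactors = FALSE)))
  ord <- order(tab$BIC)
  tab <- tab[ord, ]; fits <- fits[ord]
  tab$delta_bic <- tab$BIC - tab$BIC[1]
  near <- which(tab$delta_bic < delta)
  pick <- near[order(tab$n_par[near], tab$BIC[near])][1]
  chosen_fit <- fits[[pick]]
  wn <- white_noise_check(chosen_fit$normalized_residuals)

  # likelihood-ratio tests of the chosen model against candidates that nest
  # it (same variance structure, ARMA order componentwise >=)
  lrt <- NULL
  for (f in fits) {
    nests <- var_label(f$spec$variance) == var_label(chosen_fit$spec$variance) &&
      all(f$spec$arma >= chosen_fit$spec$arma) &&
      any(f$spec$arma > chosen_fit$spec$arma)
    if (!nests) next
    df <- f$n_par - chosen_fit$n_par
    stat <- 2 * (f$logLik - chosen_fit$logLik)
    lrt <- rbind(lrt, data.frame(
      larger = spec_label(f$spec), stat = stat, df = df,
      p = pchisq(max(stat, 0), df, lower.tail = FALSE)))
  }

  fit_reml <- NULL
  if (refit_reml) {
    sp <- chosen_fit$spec
    sp$method <- "REML"
    fit_reml <- fit_gls(sp, data, control)
  }
  structure(list(table = tab, chosen = chosen_fit$spec, fit_ml = chosen_fit,
                 fit_reml = fit_reml, white_noise = wn, lrt = lrt,
                 failures = failures, delta = delta),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Model selection over", nrow(x$table), "fitted candidates",
      sprintf("(%d failed)\n", length(x$failures)))
  print(utils::head(x$table[, c("label", "n_par", "logLik", "BIC", "delta_bic")], 8),
        row.names = FALSE)
  cat("Chosen:", spec_label(x$chosen),
      sprintf("| residual white-noise %s (Ljung-Box p = %.3f)\n",
              if (x$white_noise$pass) "PASS" else "FAIL", x$white_noise$p_value))
  invisible(x)
}

#' Drop non-significant fixed terms from a fitted model
#'
#' Removes covariates whose coefficient p-value exceeds \code{alpha}. The
#' intercept and the endogenous (density-dependence) term are kept
#' regardless unless named in \code{droppable}. The caller refits the
#' returned spec. This step is optional in the pipeline (off by default):
#' the published site models retain non-significant covariates.
#'
#' @param fit a \code{gls_fit}.
#' @param alpha significance threshold (default 0.05).
#' @param keep terms never dropped.
#' @return reduced \code{gls_spec}.
#' @export
drop_nonsignificant <- function(fit, alpha = 0.05,
                                keep = c("(Intercept)", "mft_lag")) {
  co <- fit$coefficients
  drop_terms <- co$term[co$p > alpha & !co$term %in% keep]
  if (length(drop_terms) == 0) return(fit$spec)
  rhs <- attr(stats::terms(fit$spec$fixed), "term.labels")
  rhs <- setdiff(rhs, drop_terms)
  fx <- stats::reformulate(if (length(rhs)) rhs else "1",
                           response = fit$spec$fixed[[2]])
  gls_spec(fx, fit$spec$arma, fit$spec$variance, fit$spec$method)
}

#' Write a selection report to CSV
#'
#' One row per candidate, mirroring a model-comparison table
#' (label, ARMA order, variance structure, parameter count, logLik, BIC,
#' delta BIC).
#'
#' @param x a \code{selection_result}.
#' @param path output CSV path.
#' @export
write_selection_report <- function(x, path) {
  stopifnot(inherits(x, "selection_result"))
  write.csv(x$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
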