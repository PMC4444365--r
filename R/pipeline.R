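# ---- end-to-end orchestration ----------------------------------------------

#' Per-site model structures of the published field analysis
#'
#' The ARMA order and variance structure selected for each monitored site:
#' Lahav ARMA(2,2) with nLST-proportional variance and season and year
#' strata; Sha'ar HaGai ARMA(2,2) with nLST-proportional variance and
#' season strata; Nablus ARMA(2,0) with nLST-proportional variance; Tubas
#' ARMA(1,0) with season strata; Tulkarem ARMA(2,0) with nLST-proportional
#' variance.
#'
#' @param nlst_offset offset for the nLST variance weight.
#' @return named list of \code{\link{gls_spec}}s (REML).
#' @export
field_site_specs <- function(nlst_offset = 0) {
  v <- function(...) variance_structure(...)
  list(
    Lahav = gls_spec(arma = c(2, 2),
                     variance = v(strata = c("season", "year"),
                                  covariate = "nlst", offset = nlst_offset),
                     method = "REML"),
    `Sha'ar HaGai` = gls_spec(arma = c(2, 2),
                              variance = v(strata = "season",
                                           covariate = "nlst",
                                           offset = nlst_offset),
                              method = "REML"),
    Nablus = gls_spec(arma = c(2, 0),
                      variance = v(covariate = "nlst", offset = nlst_offset),
                      method = "REML"),
    Tubas = gls_spec(arma = c(1, 0), variance = v(strata = "season"),
                     method = "REML"),
    Tulkarem = gls_spec(arma = c(2, 0),
                        variance = v(covariate = "nlst",
                                     offset = nlst_offset),
                        method = "REML"))
}

#' Reproduce the field analysis from a monitoring CSV
#'
#' Runs the full chain on a multi-site monthly CSV shaped like the
#' five-site field monitoring table (\code{site,month,ftd,days,fruit,nlst,
#' naoi}): per site, descriptive statistics, rate-of-change construction,
#' trend test, order diagnostics, the site's published model structure
#' refitted by REML, and SIMEX on the basic linear model.
#'
#' @param path CSV path.
#' @param sites site subset (default: all sites in the file).
#' @param specs named list of \code{gls_spec}s per site (default
#'   \code{\link{field_site_specs}()}; sites without an entry get BIC
#'   selection over the default grid).
#' @param sigma_u measurement-error SD for SIMEX, a single value or a
#'   named per-site vector; when NULL the SIMEX stage is skipped (supply
#'   \code{\link{estimate_sigma_u}} output, or the SD of the monthly log
#'   abundance when per-trap counts are unavailable).
#' @param seed seed for SIMEX pseudo-errors.
#' @param control a \code{\link{gls_control}}.
#' @return named list per site: \code{stats}, \code{trend},
#'   \code{diagnostics}, \code{fit} (REML \code{gls_fit}), \code{simex}
#'   (or NULL).
#' @export
reproduce_field_analysis <- function(path, sites = NULL, specs = field_site_specs(),
                                     sigma_u = NULL, seed = 1L,
                                     control = gls_control()) {
  all_series <- read_series(path, site = sites)
  if (inherits(all_series, "population_series"))
    all_series <- setNames(list(all_series), all_series$site[1])
  lapply(all_series, function(s) {
    site <- s$site[1]
    rate <- rate_of_change(s)
    diag <- diagnose_series(s)
    spec <- specs[[site]]
    fit <- if (!is.null(spec)) {
      # offset the nLST weight automatically if the site has nlst <= 0
      if (!is.null(spec$variance$covariate)) {
        v <- rate[[spec$variance$covariate]]
        if (any(v <= 0, na.rm = TRUE))
          spec$variance$offset <- -min(v, na.rm = TRUE) + 1
      }
      fit_gls(spec, rate, control)
    } else {
      select_model(rate, control = control)$fit_reml
    }
    su <- if (is.null(sigma_u)) NULL
    else if (length(sigma_u) > 1) unname(sigma_u[site]) else sigma_u
    sx <- if (!is.null(su))
      simex_fit(rate, sigma_u = su, seed = seed) else NULL
    list(stats = series_stats(s), trend = diag$trend, diagnostics = diag,
         fit = fit, simex = sx)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages over one series: \code{simulate} (when no input
#' series is given), \code{diagnose}, \code{fit} (BIC selection + REML
#' refit), \code{simex}, \code{report}. Writes per-stage CSV/JSON artifacts
#' and a manifest with the configuration and seed into \code{out_dir}.
#'
#' @param series a \code{population_series}, or NULL to simulate.
#' @param config a \code{\link{sim_config}} (used when simulating).
#' @param stages subset of \code{c("simulate","diagnose","fit","simex",
#'   "report")}.
#' @param sigma_u measurement-error SD for SIMEX (default: the config value
#'   when simulating, else skip SIMEX).
#' @param out_dir output directory (created); NULL writes nothing.
#' @param candidates candidate specs for selection.
#' @param control a \code{\link{gls_control}}.
#' @param seed seed for selection restarts and SIMEX.
#' @return list of stage results (invisibly when writing).
#' @export
run_pipeline <- function(series = NULL, config = sim_config(),
                         stages = c("simulate", "diagnose", "fit", "simex",
                                    "report"),
                         sigma_u = NULL, out_dir = NULL,
                         candidates = enumerate_candidates(),
                         control = gls_control(restarts = 1), seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  res <- list(manifest = list(timestamp = format(Sys.time(), tz = "UTC"),
                              seed = seed, stages = stages))
  if (is.null(series) && "simulate" %in% stages) {
    series <- gen_population(config)
    res$manifest$sim_config <- unclass(config)
    if (is.null(sigma_u)) sigma_u <- config$sigma_u
  }
  if (is.null(series)) stop("no input series and no simulate stage",
                            call. = FALSE)
  res$series <- series
  if (sum(!is.na(series$mft)) < 12) {
    warning("fewer than 12 usable months: analysis stages skipped",
            call. = FALSE)
    stages <- intersect(stages, "report")
  }
  rate <- rate_of_change(series)
  if ("diagnose" %in% stages) res$diagnostics <- diagnose_series(series)
  if ("fit" %in% stages)
    res$selection <- select_model(rate, candidates, control = control)
  if ("simex" %in% stages && !is.null(sigma_u) && sigma_u > 0)
    res$simex <- simex_fit(rate, sigma_u = sigma_u, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    written <- character(0)
    w <- function(name) written <<- c(written, name)
    write_series(series, file.path(out_dir, "series.csv")); w("series.csv")
    if (!is.null(res$diagnostics)) {
      write_correlogram(res$diagnostics$acf, file.path(out_dir, "acf.csv"))
      write_correlogram(res$diagnostics$prcf, file.path(out_dir, "prcf.csv"))
      tr <- res$diagnostics$trend
      write.csv(data.frame(slope = tr$slope, intercept = tr$intercept,
                           adj_r_squared = tr$adj_r_squared,
                           f_statistic = tr$f_statistic,
                           p_value = tr$p_value),
                file.path(out_dir, "trend.csv"), row.names = FALSE)
      w("acf.csv"); w("prcf.csv"); w("trend.csv")
    }
    if (!is.null(res$selection)) {
      write_selection_report(res$selection,
                             file.path(out_dir, "selection.csv"))
      write.csv(fit_to_table(res$selection$fit_reml),
                file.path(out_dir, "fit_reml.csv"), row.names = FALSE)
      w("selection.csv"); w("fit_reml.csv")
    }
    if (!is.null(res$simex)) {
      writeLines(simex_to_json(res$simex), file.path(out_dir, "simex.json"))
      w("simex.json")
    }
    res$manifest$outputs <- written
    writeLines(jsonlite::toJSON(res$manifest, auto_unbox = TRUE, digits = NA),
               file.path(out_dir, "manifest.json"))
    return(invisible(res))
  }
  res
}
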