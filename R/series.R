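#' Trap observations from a monitoring round
#'
#' Builds a validated table of raw sticky-trap collection rounds. Each row is
#' one collection round at one site: a set of traps exposed from
#' \code{period_start} to \code{period_end} whose catches are pooled.
#'
#' @param site character site label.
#' @param period_start,period_end exposure interval (Date or "YYYY-MM-DD").
#' @param n_traps number of traps exposed (>= 1).
#' @param total_catch total flies caught across the traps (>= 0).
#' @param females,males optional sex-split counts; carried along but all
#'   downstream modelling uses totals.
#' @return a \code{data.frame} of class \code{trap_obs}.
#' @export
trap_obs <- function(site, period_start, period_end, n_traps, total_catch,
                     females = NA_real_, males = NA_real_) {
  start <- as.Date(period_start)
  end <- as.Date(period_end)
  d <- data.frame(site = as.character(site), period_start = start,
                  period_end = end, n_traps = as.numeric(n_traps),
                  total_catch = as.numeric(total_catch),
                  females = as.numeric(females), males = as.numeric(males),
                  stringsAsFactors = FALSE)
  if (any(!is.finite(d$n_traps)) || any(d$n_traps < 1))
    stop("n_traps must be >= 1", call. = FALSE)
  if (any(d$n_traps != round(d$n_traps)))
    stop("n_traps must be a whole number", call. = FALSE)
  if (any(!is.finite(d$total_catch)) || any(d$total_catch < 0))
    stop("total_catch must be non-negative", call. = FALSE)
  if (any(is.na(d$period_start)) || any(is.na(d$period_end)) ||
      any(d$period_end <= d$period_start))
    stop("period_end must be after period_start", call. = FALSE)
  sexed <- !is.na(d$females) & !is.na(d$males)
  if (any(sexed & d$females + d$males > d$total_catch + 1e-9))
    stop("female + male counts exceed total_catch", call. = FALSE)
  class(d) <- c("trap_obs", "data.frame")
  d
}

#' Flies per trap per day from pooled trap rounds
#'
#' The standard abundance index for trap monitoring: total catch across all
#' traps and rounds divided by the total trap-days of exposure,
#' \eqn{FTD = \sum catch / \sum (n_{traps} \times days)}. Traps within a round
#' are assumed to share the round's exposure interval.
#'
#' @param observations a \code{trap_obs} table (one or more rounds, typically
#'   all rounds of one site-month).
#' @return flies/trap/day, a non-negative scalar.
#' @export
#' @examples
#' obs <- trap_obs("A", "2010-06-01", "2010-06-15", n_traps = 3,
#'                 total_catch = 42)
#' compute_ftd(obs) # 42 / (3 * 14) = 1
compute_ftd <- function(observations) {
  if (!inherits(observations, "trap_obs"))
    observations <- trap_obs(observations$site, observations$period_start,
                             observations$period_end, observations$n_traps,
                             observations$total_catch)
  if (nrow(observations) < 1) stop("no observations", call. = FALSE)
  days <- as.numeric(observations$period_end - observations$period_start)
  trap_days <- sum(observations$n_traps * days)
  if (trap_days <= 0) stop("zero total trap-day exposure", call. = FALSE)
  sum(observations$total_catch) / trap_days
}

#' Monthly abundance from FTD
#'
#' Scales the daily index to a monthly population estimate:
#' FTD times the number of days in the month.
#'
#' @param ftd flies/trap/day (>= 0).
#' @param days_in_month days in the calendar month (28-31).
#' @return monthly fly count estimate.
#' @export
monthly_abundance <- function(ftd, days_in_month) {
  if (any(!is.na(ftd) & ftd < 0)) stop("ftd must be non-negative", call. = FALSE)
  if (any(!is.na(days_in_month) & (days_in_month < 28 | days_in_month > 31)))
    stop("days_in_month must be in 28..31", call. = FALSE)
  ftd * days_in_month
}

#' Log abundance transform (MFT)
#'
#' \eqn{MFT = \ln(X + 1)} of the monthly count. Months with collections but
#' zero catch map to 0, keeping the log series continuous through no-capture
#' months; months with no collection at all stay \code{NA}.
#'
#' @param count monthly fly count (>= 0), NA allowed.
#' @return natural log of count + 1.
#' @export
mft_transform <- function(count) {
  if (any(!is.na(count) & count < 0))
    stop("count must be non-negative", call. = FALSE)
  log(count + 1)
}

#' Monthly population series
#'
#' Assembles an aligned monthly series for one site: the FTD abundance index,
#' the monthly count (FTD x days), its log transform (MFT), and the exogenous
#' covariates used in the rate-of-change model — night land-surface
#' temperature (nLST, degrees C), the North Atlantic Oscillation index (NAOi)
#' and host-fruit availability (0/1). Missing months (no collection) are kept
#' as explicit \code{NA} rows so that gaps are visible to downstream
#' differencing; a recorded month with zero catch has \code{ftd = 0}.
#'
#' @param site site label.
#' @param month months as "YYYY-MM" strings or Dates; must be strictly
#'   increasing with no duplicates (gaps allowed).
#' @param ftd flies/trap/day per month (NA for months with no collection).
#' @param nlst,naoi,fruit covariates per month; \code{fruit} must be 0/1/NA.
#' @param days optional days of the month; computed from the calendar when
#'   omitted.
#' @return a \code{data.frame} of class \code{population_series} with columns
#'   \code{site, month, days, ftd, monthly_count, mft, nlst, naoi, fruit,
#'   season, year}.
#' @export
population_series <- function(site, month, ftd, nlst = NA_real_,
                              naoi = NA_real_, fruit = NA_real_, days = NULL) {
  m <- parse_month(month)
  if (any(is.na(m))) stop("months must not be NA", call. = FALSE)
  if (anyDuplicated(m)) stop("duplicated months in series", call. = FALSE)
  if (is.unsorted(m, strictly = TRUE))
    stop("months must be strictly increasing", call. = FALSE)
  yr <- as.integer(format(m, "%Y"))
  mo <- as.integer(format(m, "%m"))
  if (is.null(days)) days <- mapply(days_in_month, yr, mo)
  ftd <- as.numeric(ftd)
  if (any(!is.na(ftd) & ftd < 0)) stop("ftd must be non-negative", call. = FALSE)
  fruit <- as.numeric(fruit)
  if (any(!is.na(fruit) & !fruit %in% c(0, 1)))
    stop("fruit must be 0 or 1", call. = FALSE)
  count <- monthly_abundance(ftd, days)
  d <- data.frame(site = as.character(site), month = m,
                  days = as.integer(days), ftd = ftd,
                  monthly_count = count, mft = mft_transform(count),
                  nlst = as.numeric(nlst), naoi = as.numeric(naoi),
                  fruit = fruit, season = season_of(mo),
                  year = factor(yr), stringsAsFactors = FALSE)
  class(d) <- c("population_series", "data.frame")
  d
}

#' @export
print.population_series <- function(x, ...) {
  cat(sprintf("<population_series> site '%s': %d months (%s to %s), %d missing\n",
              x$site[1], nrow(x), format_month(x$month[1]),
              format_month(x$month[nrow(x)]), sum(is.na(x$ftd))))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

# assign a trap round to a calendar month by where most exposure days fall
assign_month <- function(start, end, rule = c("majority", "start", "end")) {
  rule <- match.arg(rule)
  if (rule == "start") return(as.Date(format(start, "%Y-%m-01")))
  if (rule == "end") return(as.Date(format(end, "%Y-%m-01")))
  mapply(function(s, e) {
    s <- as.Date(s); e <- as.Date(e)
    dd <- seq(s, e - 1, by = "day") # exposure days, end exclusive
    mo <- format(dd, "%Y-%m-01")
    tab <- sort(table(mo), decreasing = TRUE)
    # ties go to the earlier month
    win <- names(tab)[tab == tab[1]]
    min(win)
  }, start, end) |> as.Date()
}

#' Aggregate raw trap rounds into a monthly population series
#'
#' Pools collection rounds of one site into months (a round is assigned to
#' the month holding the majority of its exposure days) and computes the
#' monthly FTD from the pooled trap-days.
#'
#' @param observations a \code{trap_obs} table for one site.
#' @param month_rule how rounds spanning a month boundary are assigned.
#' @return a \code{population_series} (covariates NA, to be merged by caller).
#' @export
series_from_trap_obs <- function(observations,
                                 month_rule = c("majority", "start", "end")) {
  stopifnot(inherits(observations, "trap_obs"))
  if (length(unique(observations$site)) != 1)
    stop("observations must come from a single site", call. = FALSE)
  mo <- assign_month(observations$period_start, observations$period_end,
                     match.arg(month_rule))
  months <- sort(unique(mo))
  # fill calendar gaps with NA months so gaps stay visible
  all_months <- seq(min(months), max(months), by = "month")
  ftd <- vapply(all_months, function(m) {
    idx <- mo == m
    if (!any(idx)) return(NA_real_)
    compute_ftd(observations[idx, , drop = FALSE])
  }, numeric(1))
  population_series(observations$site[1], all_months, ftd)
}

#' Read / write monthly series CSV
#'
#' CSV dialect: comma-separated UTF-8 with header
#' \code{site,month,ftd,days,fruit,nlst,naoi}, \code{month} as
#' \code{YYYY-MM}. Empty cells become explicit \code{NA} (missing), never
#' zero. Files holding several sites are split; request one with
#' \code{site} or receive a named list.
#'
#' @param path CSV file path.
#' @param site optional site filter.
#' @param format \code{"monthly"} for the dialect above, or \code{"raw"} for
#'   per-round trap data with header \code{site,start,end,n_traps,catch}.
#' @return a \code{population_series}, or a named list of them.
#' @export
read_series <- function(path, site = NULL, format = c("monthly", "raw")) {
  format <- match.arg(format)
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (format == "raw") {
    need <- c("site", "start", "end", "n_traps", "catch")
    if (!all(need %in% names(d)))
      stop("raw-trap CSV must have columns ", paste(need, collapse = ","),
           call. = FALSE)
    if (!is.null(site)) d <- d[d$site %in% site, , drop = FALSE]
    out <- lapply(split(d, d$site), function(x) {
      series_from_trap_obs(trap_obs(x$site, x$start, x$end, x$n_traps, x$catch))
    })
    return(if (length(out) == 1) out[[1]] else out)
  }
  need <- c("site", "month", "ftd")
  if (!all(need %in% names(d)))
    stop("monthly CSV must have at least columns ", paste(need, collapse = ","),
         call. = FALSE)
  extra <- setdiff(names(d),
                   c("site", "month", "ftd", "days", "fruit", "nlst", "naoi"))
  if (length(extra))
    stop("unknown column(s) in series CSV: ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (!is.null(site)) d <- d[d$site %in% site, , drop = FALSE]
  if (nrow(d) == 0) stop("no rows for requested site(s)", call. = FALSE)
  one <- function(x) {
    population_series(
      x$site[1], x$month, x$ftd,
      nlst = if ("nlst" %in% names(x)) x$nlst else NA_real_,
      naoi = if ("naoi" %in% names(x)) x$naoi else NA_real_,
      fruit = if ("fruit" %in% names(x)) x$fruit else NA_real_,
      days = if ("days" %in% names(x)) x$days else NULL)
  }
  out <- lapply(split(d, d$site), one)
  if (length(out) == 1) out[[1]] else out
}

#' @rdname read_series
#' @param series a \code{population_series}.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "population_series"))
  out <- data.frame(site = series$site, month = format_month(series$month),
                    ftd = series$ftd, days = series$days,
                    fruit = series$fruit, nlst = series$nlst,
                    naoi = series$naoi)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Descriptive statistics of a monitoring series
#'
#' Mean, SD and maximum of the monthly FTD values, and the count of observed
#' months — the summary conventionally reported for trap-monitoring series.
#'
#' @param series a \code{population_series}.
#' @return one-row data.frame with \code{site, mean_ftd, sd_ftd, max_ftd,
#'   months, zero_capture_months}.
#' @export
series_stats <- function(series) {
  stopifnot(inherits(series, "population_series"))
  f <- series$ftd[!is.na(series$ftd)]
  data.frame(site = series$site[1], mean_ftd = mean(f), sd_ftd = sd(f),
             max_ftd = max(f), months = length(f),
             zero_capture_months = sum(f == 0))
}
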