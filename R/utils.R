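#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm coef pt pf qt rnorm sd var cor complete.cases
#'   model.matrix optim pchisq resid fitted arima.sim filter Box.test
#'   setNames runif vcov printCoefmat terms reformulate model.frame
#'   model.response
#' @importFrom utils read.csv write.csv
NULL

# number of days in a calendar month, Gregorian and leap-aware
days_in_month <- function(year, month) {
  stopifnot(month >= 1, month <= 12)
  first <- as.Date(sprintf("%04d-%02d-01", year, month))
  nxt <- if (month == 12) as.Date(sprintf("%04d-01-01", year + 1)) else
    as.Date(sprintf("%04d-%02d-01", year, month + 1))
  as.integer(nxt - first)
}

# parse "YYYY-MM" (or Date) to the first day of the month
parse_month <- function(x) {
  if (inherits(x, "Date")) {
    return(as.Date(format(x, "%Y-%m-01")))
  }
  x <- as.character(x)
  ok <- grepl("^\\d{4}-\\d{2}(-\\d{2})?$", x) | is.na(x)
  if (!all(ok)) {
    stop("unparseable month value(s): ", paste(utils::head(x[!ok], 3), collapse = ", "),
         " (expected 'YYYY-MM')", call. = FALSE)
  }
  as.Date(ifelse(is.na(x), NA, paste0(substr(x, 1, 7), "-01")))
}

format_month <- function(x) format(x, "%Y-%m")

# integer month index since 0000-01, used for true time separations across gaps
month_index <- function(date) {
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  y * 12L + m
}

#' Map calendar months to meteorological seasons
#'
#' Seasons follow the northern-hemisphere meteorological convention:
#' DJF (winter), MAM (spring), JJA (summer), SON (autumn). Used as the
#' default stratification for heteroscedastic variance structures.
#'
#' @param month integer month-of-year (1-12), vectorised.
#' @return factor with levels \code{DJF, MAM, JJA, SON}.
#' @export
#' @examples
#' season_of(c(1, 4, 7, 10))
season_of <- function(month) {
  month <- as.integer(month)
  if (any(is.na(month)) || any(month < 1L | month > 12L)) {
    stop("month must be in 1..12", call. = FALSE)
  }
  lab <- c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA",
           "JJA", "JJA", "SON", "SON", "SON", "DJF")
  factor(lab[month], levels = c("DJF", "MAM", "JJA", "SON"))
}
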