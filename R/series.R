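# Shared infrastructure: classed error conditions, the annual-series
# container, and period (year-window) handling used by every stage.

stop_dendroiso <- function(msg, class, call. = FALSE) {
  cond <- errorCondition(msg,
                         class = c(paste0("dendroiso_", class), "dendroiso_error"))
  stop(cond)
}

#' Annual series
#'
#' The universal currency of the pipeline: a year-indexed table with one real
#' value per year.  Units depend on context: isotope ratios in per mil
#' (VPDB for carbon, VSMOW for oxygen), precipitation in mm, temperature in
#' degrees C, or a dimensionless circulation index.
#'
#' @param year integer calendar years CE.
#' @param value numeric values, one per year.
#' @return a data frame of class \code{annual_series} with columns
#'   \code{year} and \code{value}, sorted by year.
#' @examples
#' annual_series(2000:2004, rnorm(5))
#' @export
annual_series <- function(year, value) {
  if (length(year) != length(value))
    stop_dendroiso("year and value must have equal length", "invalid_argument")
  year <- as.integer(year)
  if (anyNA(year))
    stop_dendroiso("years must be integer-valued and non-missing", "invalid_argument")
  if (anyDuplicated(year))
    stop_dendroiso("duplicate years in annual series", "integrity")
  value <- as.numeric(value)
  o <- order(year)
  structure(data.frame(year = year[o], value = value[o], row.names = NULL),
            class = c("annual_series", "data.frame"))
}

#' Coerce to an annual series
#'
#' @param x an object with a year-indexed value column: an
#'   \code{annual_series}, a \code{\link{build_chronology}} result (the
#'   per-year mean is taken), a reconstruction, or any data frame with
#'   \code{year} and \code{value} columns.
#' @param ... unused.
#' @return an \code{annual_series}.
#' @export
as_annual_series <- function(x, ...) UseMethod("as_annual_series")

#' @export
as_annual_series.annual_series <- function(x, ...) x

#' @export
as_annual_series.chronology <- function(x, ...) annual_series(x$year, x$mean)

#' @export
as_annual_series.data.frame <- function(x, ...) {
  if (!all(c("year", "value") %in% names(x)))
    stop_dendroiso("data frame needs 'year' and 'value' columns", "invalid_argument")
  annual_series(x$year, x$value)
}

#' @export
as_annual_series.numeric <- function(x, ...) {
  yrs <- as.integer(names(x))
  if (anyNA(yrs))
    stop_dendroiso("numeric input must be named by year", "invalid_argument")
  annual_series(yrs, unname(x))
}

# Expand a period specification into a sorted vector of years.  A length-2
# vector is a closed range c(from, to); longer vectors are explicit year
# lists; NULL passes through (meaning "all available years").
period_years <- function(period) {
  if (is.null(period)) return(NULL)
  period <- as.integer(period)
  if (anyNA(period))
    stop_dendroiso("period years must be integers", "invalid_argument")
  if (length(period) == 2L) {
    if (period[2L] < period[1L])
      stop_dendroiso("period end precedes period start", "invalid_argument")
    return(period[1L]:period[2L])
  }
  sort(unique(period))
}

# Restrict an annual series to a period (NULL = keep all years).
series_window <- function(x, period = NULL) {
  x <- as_annual_series(x)
  if (is.null(period)) return(x)
  x[x$year %in% period_years(period), , drop = FALSE]
}

# Inner-join two annual series on year -> data.frame(year, x, y).
merge_series <- function(a, b) {
  a <- as_annual_series(a)
  b <- as_annual_series(b)
  yrs <- intersect(a$year, b$year)
  yrs <- sort(yrs)
  data.frame(year = yrs,
             x = a$value[match(yrs, a$year)],
             y = b$value[match(yrs, b$year)])
}

# Contiguity check used by smoothing and table validators.
is_contiguous <- function(years) {
  length(years) <= 1L || all(diff(sort(years)) == 1L)
}

# Stable non-cryptographic hash of an R object, for audit headers.
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
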