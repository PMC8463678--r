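# Hamming-window smoothing, sigma-threshold extreme-year detection,
# period contrasts, and matching of cold extremes to a volcanic eruption
# catalog.

#' Hamming window weights
#'
#' \code{w_k = 0.54 - 0.46 * cos(2 * pi * k / (M - 1))}, k = 0..M-1,
#' normalized to sum to one.
#'
#' @param m window length (odd, >= 3).
#' @return numeric vector of m weights summing to 1.
#' @export
hamming_weights <- function(m) {
  if (m < 3L || m %% 2L == 0L)
    stop_dendroiso("window length must be an odd integer >= 3", "invalid_argument")
  k <- 0:(m - 1L)
  w <- 0.54 - 0.46 * cos(2 * pi * k / (m - 1L))
  w / sum(w)
}

#' Smooth an annual series with a centered Hamming window
#'
#' Weighted moving average with Hamming weights.  At the series edges the
#' window is truncated to the available years and its weights renormalized
#' (no padding: no values are fabricated beyond the series).  A constant
#' series is returned unchanged, and the output never leaves the input's
#' range (the weights are positive and sum to one).
#'
#' @param series an \code{annual_series} / \code{chronology} /
#'   \code{reconstruction} with contiguous years, or a plain numeric
#'   vector.
#' @param window_length odd window length, >= 3 and <= the series length
#'   (41 years is typical for chronology display, 101 for long
#'   reconstructions).
#' @return the smoothed series (same shape as the input: an
#'   \code{annual_series}, or a numeric vector for numeric input).
#' @export
hamming_smooth <- function(series, window_length) {
  numeric_in <- is.numeric(series) && is.null(dim(series))
  if (numeric_in) {
    x <- as.numeric(series); yrs <- seq_along(x)
  } else {
    s <- as_annual_series(series)
    if (!is_contiguous(s$year))
      stop_dendroiso("series years must be contiguous for smoothing",
                     "invalid_argument")
    x <- s$value; yrs <- s$year
  }
  n <- length(x)
  m <- as.integer(window_length)
  if (m < 3L || m %% 2L == 0L || m > n)
    stop_dendroiso("window length must be odd, >= 3, and <= the series length",
                   "invalid_argument")
  w <- hamming_weights(m)
  half <- (m - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    ww <- w[(lo - i + half + 1L):(hi - i + half + 1L)]
    out[i] <- sum(ww * x[lo:hi]) / sum(ww)
  }
  if (numeric_in) out else annual_series(yrs, out)
}

#' Detect sigma-threshold extreme years
#'
#' Flags every year whose standardized anomaly relative to the
#' reference-period mean and sample SD reaches the smallest threshold
#' (|z| >= 2 by default), and labels the highest threshold attained
#' (e.g. 3 sigma).  The sign refers to the series' own units (for a
#' precipitation reconstruction, negative = dry; for an AO reconstruction,
#' negative = negative phase / cold), not to the raw isotope sign.
#'
#' @param series an annual series or compatible object.
#' @param reference_period period for the reference mean/SD (default: the
#'   whole series).
#' @param thresholds sigma thresholds, ascending (default \code{c(2, 3)}).
#' @return data frame of class \code{extreme_years} with columns
#'   \code{year}, \code{value}, \code{z}, \code{sign}
#'   (\code{"positive"}/\code{"negative"}), \code{level} (the highest
#'   threshold attained, in sigma units).
#' @export
detect_extremes <- function(series, reference_period = NULL,
                            thresholds = c(2, 3)) {
  s <- as_annual_series(series)
  ref <- series_window(s, reference_period)
  if (nrow(ref) < 2L)
    stop_dendroiso("reference period must contain at least two years", "coverage")
  m <- mean(ref$value); sd_ref <- stats::sd(ref$value)
  if (sd_ref == 0) stop_dendroiso("reference SD is zero", "degenerate")
  thresholds <- sort(thresholds)
  z <- (s$value - m) / sd_ref
  hit <- abs(z) >= thresholds[1L]
  lev <- vapply(abs(z[hit]), function(a) max(thresholds[thresholds <= a]), 0)
  structure(data.frame(year = s$year[hit], value = s$value[hit], z = z[hit],
                       sign = ifelse(z[hit] >= 0, "positive", "negative"),
                       level = lev, row.names = NULL),
            class = c("extreme_years", "data.frame"),
            reference = list(mean = m, sd = sd_ref),
            thresholds = thresholds)
}

#' Contrast two periods of a series
#'
#' Per-period means and per-period OLS linear trends (r-squared and the
#' two-sided p-value of the slope), for statements like "precipitation
#' fell from X mm (early period) to Y mm (late period)".
#'
#' @param series an annual series or compatible object.
#' @param period_a,period_b period specs, both within coverage.
#' @return list of class \code{period_contrast}: \code{mean_a},
#'   \code{mean_b}, \code{difference} (b - a), and \code{trend_a} /
#'   \code{trend_b}, each a list with \code{slope}, \code{r2}, \code{p},
#'   \code{n}.
#' @export
period_contrast <- function(series, period_a, period_b) {
  s <- as_annual_series(series)
  one <- function(period) {
    w <- series_window(s, period)
    if (nrow(w) == 0L)
      stop_dendroiso("period does not overlap the series", "coverage")
    trend <- if (nrow(w) >= 3L && stats::var(w$value) > 0) {
      fit <- stats::lm(value ~ year, data = w)
      sm <- suppressWarnings(summary(fit))  # exact trends warn harmlessly
      list(slope = unname(stats::coef(fit)[2L]), r2 = sm$r.squared,
           p = sm$coefficients[2L, 4L], n = nrow(w))
    } else {
      list(slope = if (nrow(w) >= 2L) unname(stats::coef(stats::lm(value ~ year, data = w))[2L]) else NA_real_,
           r2 = if (stats::var(w$value) == 0) 0 else NA_real_,
           p = NA_real_, n = nrow(w))
    }
    list(mean = mean(w$value), trend = trend)
  }
  a <- one(period_a); b <- one(period_b)
  structure(list(mean_a = a$mean, mean_b = b$mean,
                 difference = b$mean - a$mean,
                 trend_a = a$trend, trend_b = b$trend),
            class = "period_contrast")
}

#' @export
print.period_contrast <- function(x, ...) {
  cat(sprintf("Period A: mean %.2f (trend r2 = %.2f, p = %.3g, n = %d)\n",
              x$mean_a, x$trend_a$r2, x$trend_a$p, x$trend_a$n))
  cat(sprintf("Period B: mean %.2f (trend r2 = %.2f, p = %.3g, n = %d)\n",
              x$mean_b, x$trend_b$r2, x$trend_b$p, x$trend_b$n))
  cat(sprintf("Difference (B - A): %.2f\n", x$difference))
  invisible(x)
}

#' Match cold extremes to a volcanic eruption catalog
#'
#' For each eruption at or above the VEI cutoff, lists the extreme years
#' falling within \code{eruption_year + lag_window} (default 0 to 3 years
#' after the eruption, covering delayed radiative cooling).  Pass the
#' negative-sign subset of \code{\link{detect_extremes}} output as the
#' cold extremes.
#'
#' @param cold_extremes an \code{extreme_years} table (or any data frame
#'   with a \code{year} column).
#' @param catalog eruption catalog: data frame with \code{year},
#'   \code{name}, \code{vei}.
#' @param min_vei minimum Volcanic Explosivity Index (default 4).
#' @param lag_window integer lag range \code{c(from, to)} relative to the
#'   eruption year.
#' @return data frame of class \code{volcanic_matches} with one row per
#'   qualifying eruption: \code{year}, \code{name}, \code{vei},
#'   \code{n_matched}, \code{matched_years} (comma-separated).  Attributes
#'   \code{n_matched_eruptions}, \code{n_unmatched_eruptions},
#'   \code{matched_extreme_years}.
#' @export
match_volcanic <- function(cold_extremes, catalog, min_vei = 4,
                           lag_window = c(0L, 3L)) {
  if (is.null(catalog) || nrow(catalog) == 0L)
    stop_dendroiso("eruption catalog is empty", "invalid_argument")
  cand <- catalog[catalog$vei >= min_vei, , drop = FALSE]
  ex_years <- sort(unique(cold_extremes$year))
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    win <- (cand$year[i] + lag_window[1L]):(cand$year[i] + lag_window[2L])
    hit <- intersect(ex_years, win)
    data.frame(year = cand$year[i], name = cand$name[i], vei = cand$vei[i],
               n_matched = length(hit),
               matched_years = paste(hit, collapse = ","))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(year = integer(), name = character(), vei = numeric(),
               n_matched = integer(), matched_years = character())
  all_hits <- sort(unique(unlist(
    lapply(rows, function(r) if (nzchar(r$matched_years))
      as.integer(strsplit(r$matched_years, ",")[[1L]]) else integer()))))
  structure(out, class = c("volcanic_matches", "data.frame"),
            n_matched_eruptions = sum(out$n_matched > 0),
            n_unmatched_eruptions = sum(out$n_matched == 0),
            matched_extreme_years = all_hits)
}
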