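# Atmospheric d13C (Suess-effect) correction.
#
# Fossil-fuel and biomass combustion has lowered the d13C of atmospheric
# CO2 since ~1850; that decline is imprinted on raw tree-ring d13C.  The
# correction subtracts, for each year at or after the reference year, the
# difference between the atmospheric value that year and its pre-industrial
# (reference-year) value.  Years before the reference year are untouched,
# and no other industrial-era correction is applied.

#' Correct a d13C series for the atmospheric Suess decline
#'
#' \code{corrected(t) = raw(t) - (atm(t) - atm(ref_year))} for
#' \code{t >= ref_year}; earlier years pass through unchanged.  Since the
#' atmospheric record declines after the reference year, the correction is
#' non-negative there (corrected >= raw).  The returned correction record
#' makes the operation exactly invertible.
#'
#' @param raw an \code{annual_series}, \code{chronology}, or compatible
#'   data frame of raw d13C values (per mil VPDB).
#' @param atm an \code{atm_record} (columns \code{year}, \code{d13c_atm})
#'   covering the reference year and every series year at or after it.
#'   Missing needed years are a hard error; nothing is interpolated.
#' @param ref_year pre-industrial reference year (default 1850).
#' @return a list with \code{corrected} (same class as the input: a
#'   corrected \code{chronology} keeps its depth columns, otherwise an
#'   \code{annual_series}) and \code{record}, a data frame
#'   \code{(year, delta_applied)} where \code{delta_applied} is the amount
#'   subtracted (zero before \code{ref_year}).
#' @examples
#' atm <- gen_atm_record(c(1800, 2009))
#' raw <- annual_series(1990:2009, rnorm(20, -24))
#' cs <- correct_suess(raw, atm)
#' all.equal(raw$value, cs$corrected$value + cs$record$delta_applied)
#' @export
correct_suess <- function(raw, atm, ref_year = 1850L) {
  is_chron <- inherits(raw, "chronology")
  s <- as_annual_series(raw)
  delta <- suess_term(s$year, atm, ref_year = ref_year)
  record <- data.frame(year = s$year, delta_applied = delta)
  if (is_chron) {
    corrected <- raw
    corrected$mean <- raw$mean - delta[match(raw$year, s$year)]
    attr(corrected, "mean_full") <- mean(corrected$mean)
    attr(corrected, "sd_full") <- stats::sd(corrected$mean)
    attr(corrected, "se_full") <- stats::sd(corrected$mean) / sqrt(nrow(corrected))
  } else {
    corrected <- annual_series(s$year, s$value - delta)
  }
  list(corrected = corrected, record = record)
}
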