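# CSV interchange (plain CSV with commented metadata headers), packaged
# fixtures (published transfer-function coefficients and the eruption
# catalog), and validated readers for each table shape.

# Read a CSV with '#' metadata comments, checking required columns and
# reporting malformed rows by file line number.
read_checked_csv <- function(path, required, numeric_cols = required) {
  if (!file.exists(path))
    stop_dendroiso(sprintf("file not found: %s", path), "io")
  lines <- readLines(path, warn = FALSE)
  header_line <- which(!startsWith(trimws(lines), "#") & nzchar(trimws(lines)))[1L]
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop_dendroiso(sprintf("%s: missing column(s): %s", path,
                           paste(miss, collapse = ", ")), "parse")
  for (col in intersect(numeric_cols, names(d))) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]) & nzchar(trimws(as.character(d[[col]]))))
    if (length(bad))
      stop_dendroiso(sprintf("%s: malformed value in column '%s' at line %d",
                             path, col, header_line + bad[1L]), "parse")
    if (anyNA(v))
      stop_dendroiso(sprintf("%s: missing value in column '%s' at line %d",
                             path, col, header_line + which(is.na(v))[1L]),
                     "parse")
    d[[col]] <- v
  }
  d
}

# Write a data frame as CSV with commented metadata header lines.
write_csv_meta <- function(x, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta))
    writeLines(sprintf("# %s: %s", names(meta),
                       vapply(meta, function(v) paste(format(v), collapse = " "), "")),
               con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an annual series from CSV
#'
#' Expects columns \code{year,value}; lines starting with \code{#} are
#' metadata comments.  An empty file with a header yields an empty series.
#'
#' @param path CSV path.
#' @return an \code{annual_series}.
#' @export
read_annual_csv <- function(path) {
  d <- read_checked_csv(path, c("year", "value"))
  annual_series(d$year, d$value)
}

#' Write an annual series (or reconstruction) to CSV
#'
#' @param x an \code{annual_series}, \code{chronology} or
#'   \code{reconstruction}.
#' @param path output path.
#' @param meta named list written as \code{# key: value} header comments.
#' @return the path, invisibly.
#' @export
write_annual_csv <- function(x, path, meta = list()) {
  write_csv_meta(as.data.frame(x), path, meta)
}

#' Read per-tree isotope series from tidy CSV
#'
#' Expects columns \code{year,tree_id,value} and optionally
#' \code{pith_year} (constant within a tree).  Duplicate (year, tree_id)
#' rows and within-tree year gaps are integrity errors.
#'
#' @param path CSV path.
#' @param scale isotope scale tag applied to all trees.
#' @return a list of \code{\link{tree_series}}.
#' @export
read_tree_csv <- function(path, scale = c("d13C", "d18O")) {
  scale <- match.arg(scale)
  d <- read_checked_csv(path, c("year", "tree_id", "value"),
                        numeric_cols = c("year", "value"))
  if (nrow(d) == 0L) return(list())
  if (anyDuplicated(d[, c("year", "tree_id")]))
    stop_dendroiso(sprintf("%s: duplicated (year, tree_id) rows", path),
                   "integrity")
  lapply(split(d, d$tree_id), function(td) {
    td <- td[order(td$year), ]
    if (!is_contiguous(td$year))
      stop_dendroiso(sprintf("tree %s has year gaps (missing rings)",
                             td$tree_id[1L]), "integrity")
    pith <- if ("pith_year" %in% names(td)) as.integer(td$pith_year[1L]) else NA_integer_
    tree_series(td$tree_id[1L], td$year[1L], td$value, pith_year = pith,
                scale = scale)
  })
}

#' Write per-tree series to tidy CSV
#'
#' @param trees list of \code{\link{tree_series}}.
#' @param path output path.
#' @param meta metadata header entries.
#' @return the path, invisibly.
#' @export
write_tree_csv <- function(trees, path, meta = list()) {
  d <- do.call(rbind, lapply(trees, function(t)
    data.frame(year = t$years, tree_id = t$tree_id, value = t$values,
               pith_year = t$pith_year)))
  write_csv_meta(d, path, meta)
}

#' Read a monthly climate table from CSV
#'
#' Expects long-format columns
#' \code{year,month,temperature,precipitation,ao}; every year must carry
#' all 12 months, years must be contiguous, and precipitation
#' non-negative.
#'
#' @param path CSV path.
#' @return a \code{climate_table}.
#' @export
read_climate_csv <- function(path) {
  d <- read_checked_csv(path, c("year", "month", "temperature",
                                "precipitation", "ao"))
  d <- d[order(d$year, d$month), ]
  counts <- table(d$year)
  if (any(counts != 12L))
    stop_dendroiso(sprintf("%s: every year needs all 12 months", path),
                   "integrity")
  if (!is_contiguous(unique(d$year)))
    stop_dendroiso(sprintf("%s: climate years must be contiguous", path),
                   "integrity")
  if (any(d$precipitation < 0))
    stop_dendroiso(sprintf("%s: negative precipitation", path), "integrity")
  structure(as.data.frame(d, row.names = NULL),
            class = c("climate_table", "data.frame"))
}

#' Read an atmospheric d13C record from CSV
#'
#' @param path CSV with columns \code{year,d13c_atm}.
#' @return an \code{atm_record}.
#' @export
read_atm_csv <- function(path) {
  d <- read_checked_csv(path, c("year", "d13c_atm"))
  if (!is_contiguous(d$year))
    stop_dendroiso(sprintf("%s: atmospheric record years must be contiguous",
                           path), "integrity")
  structure(data.frame(year = as.integer(d$year), d13c_atm = d$d13c_atm),
            class = c("atm_record", "data.frame"))
}

#' Read a volcanic eruption catalog from CSV
#'
#' @param path CSV with columns \code{year,name,vei}.
#' @return data frame with \code{year}, \code{name}, \code{vei}.
#' @export
read_eruptions_csv <- function(path) {
  d <- read_checked_csv(path, c("year", "name", "vei"),
                        numeric_cols = c("year", "vei"))
  if (any(d$vei < 0 | d$vei > 8))
    stop_dendroiso(sprintf("%s: VEI must lie in [0, 8]", path), "integrity")
  data.frame(year = as.integer(d$year), name = as.character(d$name),
             vei = d$vei)
}

#' Packaged catalog of major volcanic eruptions (VEI >= 4)
#'
#' The large tropical and extratropical eruptions commonly associated with
#' Northern-Hemisphere cold anomalies over 500-2009 CE.
#'
#' @return data frame with \code{year}, \code{name}, \code{vei}.
#' @export
eruption_catalog <- function() {
  read_eruptions_csv(system.file("extdata", "volcanic_eruptions.csv",
                                 package = "dendroiso", mustWork = TRUE))
}

#' Published transfer-function fixtures for the Taimyr reconstructions
#'
#' The single-proxy transfer equations for July precipitation from the
#' d13C chronology and the May Arctic Oscillation index from the d18O
#' chronology, with their additive \code{+0.15} offset preserved verbatim
#' as \code{extra_offset}.  These models carry no residual estimate, so
#' reconstructions made with them have no confidence band.
#'
#' @return named list of \code{transfer_model} objects
#'   (\code{july_precip_d13c}, \code{ao_may_d18o}).
#' @examples
#' m <- taimyr_models()$july_precip_d13c
#' apply_transfer(m, annual_series(2000, -24.0))$value  # 43.711
#' @export
taimyr_models <- function() {
  d <- read_checked_csv(system.file("extdata", "transfer_models.csv",
                                    package = "dendroiso", mustWork = TRUE),
                        c("name", "slope", "intercept", "offset"),
                        numeric_cols = c("slope", "intercept", "offset"))
  out <- lapply(seq_len(nrow(d)), function(i)
    transfer_model(slope = d$slope[i], intercept = d$intercept[i],
                   extra_offset = d$offset[i], label = d$name[i]))
  stats::setNames(out, d$name)
}
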