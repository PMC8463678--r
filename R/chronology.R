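# Per-tree series and replication-gated mean chronologies.
#
# A tree series is one cross-dated tree's annual isotope values with no
# internal gaps ("no missing rings"); a chronology is the per-year
# arithmetic mean across all trees covering that year, reported only where
# the sample depth reaches the replication gate (>= 4 trees by default).

#' Construct a tree series
#'
#' @param tree_id opaque label.
#' @param first_year calendar year CE of the first ring in \code{values}.
#' @param values isotope values, one per consecutive year; must be finite.
#' @param pith_year calendar year of ring age 0, if known (\code{NA} for a
#'   broken-stem series whose pith was not reached).
#' @param scale isotope scale tag: \code{"d13C"} (VPDB) or \code{"d18O"}
#'   (VSMOW).
#' @return an object of class \code{tree_series}: a list with fields
#'   \code{tree_id}, \code{years}, \code{values}, \code{pith_year},
#'   \code{scale}.
#' @export
tree_series <- function(tree_id, first_year, values,
                        pith_year = NA_integer_, scale = c("d13C", "d18O")) {
  scale <- match.arg(scale)
  if (length(values) < 1L)
    stop_dendroiso("tree series must contain at least one ring", "empty_series")
  if (!all(is.finite(values)))
    stop_dendroiso("tree series values must be finite (no missing rings)",
                   "integrity")
  first_year <- as.integer(first_year)
  structure(list(tree_id = as.character(tree_id),
                 years = first_year + seq_along(values) - 1L,
                 values = as.numeric(values),
                 pith_year = as.integer(pith_year),
                 scale = scale),
            class = "tree_series")
}

#' @export
print.tree_series <- function(x, ...) {
  cat(sprintf("Tree %s (%s): %d-%d, %d rings, pith %s\n",
              x$tree_id, x$scale, min(x$years), max(x$years),
              length(x$values),
              if (is.na(x$pith_year)) "unknown" else x$pith_year))
  invisible(x)
}

#' Remove the juvenile period from a tree series
#'
#' Drops the first \code{n_exclude} rings by ring age, counted from the
#' pith year when known, otherwise from the start of the series.  The
#' juvenile period carries non-climatic isotopic trends and is excluded
#' from chronology building.
#'
#' @param tree a \code{\link{tree_series}}.
#' @param n_exclude number of juvenile rings to remove (default 50).
#' @return the trimmed \code{tree_series}.
#' @examples
#' tr <- tree_series("a", 1500, rnorm(351), pith_year = 1500)
#' range(trim_juvenile(tr)$years)  # 1550 1850
#' @export
trim_juvenile <- function(tree, n_exclude = 50L) {
  base <- if (!is.na(tree$pith_year)) tree$pith_year else tree$years[1L]
  keep <- (tree$years - base) >= n_exclude
  if (!any(keep))
    stop_dendroiso(sprintf("tree %s has no rings older than the %d-year juvenile period",
                           tree$tree_id, n_exclude), "empty_series")
  tree_series(tree$tree_id, tree$years[keep][1L], tree$values[keep],
              pith_year = tree$pith_year, scale = tree$scale)
}

#' Build a replication-gated mean chronology
#'
#' Per-year arithmetic mean across all trees covering that year (trees
#' weighted equally).  Years whose sample depth falls below
#' \code{min_replication} are dropped, not interpolated.  Summary
#' statistics over the retained years are attached: the chronology mean,
#' its SD, and SE = SD / sqrt(n years), all using the sample (n-1) SD
#' convention.
#'
#' @param trees a list of \code{\link{tree_series}} on a common isotope
#'   scale (e.g. the output of \code{\link{gen_tree_series}}).
#' @param min_replication minimum trees per year (default 4).
#' @return a data frame of class \code{chronology} with columns
#'   \code{year}, \code{mean}, \code{sample_depth}, \code{sd_trees}
#'   (between-tree SD within the year, NA where depth is 1), and
#'   attributes \code{mean_full}, \code{sd_full}, \code{se_full},
#'   \code{scale}, \code{depth_all} (sample depth over the full union of
#'   coverage, before gating).
#' @export
build_chronology <- function(trees, min_replication = 4L) {
  if (length(trees) < 1L)
    stop_dendroiso("no trees supplied", "invalid_argument")
  scales <- unique(vapply(trees, function(t) t$scale, ""))
  if (length(scales) != 1L)
    stop_dendroiso("trees mix isotope scales; build one chronology per scale",
                   "integrity")
  years <- sort(unique(unlist(lapply(trees, function(t) t$years))))
  vals <- matrix(NA_real_, length(years), length(trees))
  for (j in seq_along(trees)) {
    idx <- match(trees[[j]]$years, years)
    vals[idx, j] <- trees[[j]]$values
  }
  depth <- rowSums(!is.na(vals))
  mean_y <- rowMeans(vals, na.rm = TRUE)
  sd_y <- apply(vals, 1L, stats::sd, na.rm = TRUE)
  keep <- depth >= min_replication
  if (!any(keep))
    stop_dendroiso(sprintf("no year reaches the replication gate of %d trees",
                           min_replication), "empty_chronology")
  out <- data.frame(year = years[keep], mean = mean_y[keep],
                    sample_depth = as.integer(depth[keep]),
                    sd_trees = sd_y[keep], row.names = NULL)
  structure(out,
            class = c("chronology", "data.frame"),
            mean_full = mean(out$mean),
            sd_full = stats::sd(out$mean),
            se_full = stats::sd(out$mean) / sqrt(nrow(out)),
            scale = scales,
            depth_all = data.frame(year = years, sample_depth = as.integer(depth)))
}

#' @export
print.chronology <- function(x, ...) {
  cat(sprintf("%s chronology: %d years (%d-%d), depth %d-%d\n",
              attr(x, "scale"), nrow(x), min(x$year), max(x$year),
              min(x$sample_depth), max(x$sample_depth)))
  cat(sprintf("  mean %.2f, SD %.3f, SE %.4f (over retained years)\n",
              attr(x, "mean_full"), attr(x, "sd_full"), attr(x, "se_full")))
  invisible(x)
}

#' Standard score of a value or year against a reference period
#'
#' \code{(x - mean_ref) / sd_ref} with the reference mean and sample SD
#' computed over \code{reference_period} of the series.  Used to express
#' chronology or reconstruction anomalies in sigma units (e.g. a -3 sigma
#' isotope minimum).
#'
#' @param series a \code{chronology}, \code{annual_series}, or compatible
#'   data frame.
#' @param year year to score (ignored when \code{value} is given).
#' @param value explicit value to score instead of a stored year.
#' @param reference_period period spec for the reference statistics
#'   (default: all years of the series).
#' @return the score in sigma units.
#' @export
zscore <- function(series, year = NULL, value = NULL, reference_period = NULL) {
  s <- as_annual_series(series)
  ref <- series_window(s, reference_period)
  if (nrow(ref) < 2L)
    stop_dendroiso("reference period must contain at least two years", "coverage")
  m <- mean(ref$value)
  sd_ref <- stats::sd(ref$value)
  if (sd_ref == 0)
    stop_dendroiso("reference SD is zero", "degenerate")
  if (is.null(value)) {
    if (is.null(year))
      stop_dendroiso("supply either a year or a value", "invalid_argument")
    idx <- match(as.integer(year), s$year)
    if (anyNA(idx))
      stop_dendroiso("year not covered by the series", "missing_year")
    value <- s$value[idx]
  }
  (value - m) / sd_ref
}

#' Summary statistics of a series over a period
#'
#' @param series a \code{chronology}, \code{annual_series}, or compatible
#'   data frame.
#' @param period period spec (default: all years).
#' @return a list with \code{mean}, \code{sd} (sample SD), \code{se}
#'   (= sd / sqrt(n)), and \code{n} (years used).
#' @export
summary_stats <- function(series, period = NULL) {
  w <- series_window(series, period)
  if (nrow(w) == 0L)
    stop_dendroiso("period does not overlap the series", "empty_period")
  n <- nrow(w)
  s <- if (n > 1L) stats::sd(w$value) else 0
  list(mean = mean(w$value), sd = s, se = s / sqrt(n), n = n)
}
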