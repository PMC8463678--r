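# Pseudoproxy generator: synthetic monthly climate, an atmospheric d13C
# record with an industrial-era (Suess) decline, and per-tree isotope
# series carrying a known climate signal, tree offsets, juvenile trends,
# and measurement noise.  Every ground-truth parameter is recorded so that
# downstream stages can be validated against it.

# Monthly climatology of a subarctic continental station (Taimyr region):
# annual mean near -12.8 degC with a July maximum of 12.6 degC, and about
# 280 mm of annual precipitation concentrated in summer (July ~58 mm).
khatanga_climatology <- function() {
  m <- 1:12
  list(
    temperature   = -12.8 + 25.4 * cos(2 * pi * (m - 7) / 12),
    precipitation = c(10, 10, 12, 15, 20, 35, 58, 45, 30, 20, 15, 10),
    ao            = rep(0, 12)
  )
}

# Derive a per-tree substream seed from the global seed so that each tree's
# random draws are isolated.  Kept below 2^31 - 2 so that +1 offsets are
# still valid seeds.
tree_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 9973) %% 2147483629)
}

# Stationary AR(1) series of length n with autoregressive coefficient phi
# and innovation standard deviation sd; the first value is drawn from the
# stationary distribution.
ar1_series <- function(n, phi, sd) {
  x0 <- stats::rnorm(1, 0, sd / sqrt(1 - phi^2))
  innov <- stats::rnorm(n, 0, sd)
  as.numeric(stats::filter(innov, phi, method = "recursive", init = x0))
}

#' Generate a synthetic monthly climate table
#'
#' Monthly temperature, precipitation and Arctic Oscillation (AO) index
#' series are AR(1) anomalies about a fixed subarctic monthly climatology
#' (July mean temperature 12.6 degC, ~280 mm annual precipitation with a
#' July peak of 58 mm, zero-mean AO).  In an eruption year and the year
#' after, temperature anomalies are depressed by \code{volcanic_cooling}
#' and the AO index is shifted by \code{volcanic_ao_shift} (a negative AO
#' excursion, as observed after large tropical eruptions).
#'
#' @param years a length-2 range \code{c(from, to)} or explicit vector of
#'   calendar years CE.
#' @param ar1_coeff lag-1 autocorrelation of the yearly anomaly process for
#'   every month-series, in [0, 1).
#' @param innovation_sd innovation SD of the temperature anomalies, degC.
#' @param precip_rel_sd innovation SD of the relative (multiplicative)
#'   precipitation anomalies; monthly precipitation is clipped at zero.
#' @param ao_sd innovation SD of the AO index anomalies.
#' @param volcanic_catalog optional data frame with columns \code{year},
#'   \code{name}, \code{vei} (see \code{\link{eruption_catalog}}).
#' @param volcanic_cooling temperature depression (degC) applied in an
#'   eruption year and the following year.
#' @param volcanic_ao_shift additive AO shift applied over the same window
#'   (negative for a negative-phase excursion).
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @return a data frame of class \code{climate_table} in long format with
#'   columns \code{year}, \code{month}, \code{temperature},
#'   \code{precipitation}, \code{ao}.
#' @examples
#' cl <- gen_climate(c(1950, 2009), seed = 1)
#' head(cl)
#' @export
gen_climate <- function(years, ar1_coeff = 0.2, innovation_sd = 1.5,
                        precip_rel_sd = 0.23, ao_sd = 1,
                        volcanic_catalog = NULL, volcanic_cooling = 1.5,
                        volcanic_ao_shift = -1.5, seed = 1L) {
  yrs <- period_years(years)
  if (is.null(yrs) || length(yrs) == 0L)
    stop_dendroiso("empty year range", "invalid_argument")
  if (length(yrs) == 1L) yrs <- yrs  # single year is allowed
  if (!is_contiguous(yrs))
    stop_dendroiso("climate years must be contiguous", "invalid_argument")
  if (ar1_coeff < 0 || ar1_coeff >= 1)
    stop_dendroiso("ar1_coeff must lie in [0, 1)", "invalid_argument")
  n <- length(yrs)
  clim <- khatanga_climatology()

  set.seed(as.integer(as.numeric(seed) %% 2147483647))
  temp <- matrix(0, n, 12)
  prec <- matrix(0, n, 12)
  ao   <- matrix(0, n, 12)
  for (m in 1:12) temp[, m] <- clim$temperature[m] + ar1_series(n, ar1_coeff, innovation_sd)
  for (m in 1:12) prec[, m] <- pmax(0, clim$precipitation[m] *
                                       (1 + ar1_series(n, ar1_coeff, precip_rel_sd)))
  for (m in 1:12) ao[, m]   <- clim$ao[m] + ar1_series(n, ar1_coeff, ao_sd)

  if (!is.null(volcanic_catalog) && nrow(volcanic_catalog) > 0) {
    for (ey in volcanic_catalog$year) {
      hit <- which(yrs %in% c(ey, ey + 1L))
      if (length(hit)) {
        temp[hit, ] <- temp[hit, ] - volcanic_cooling
        ao[hit, ]   <- ao[hit, ] + volcanic_ao_shift
      }
    }
  }

  out <- data.frame(
    year = rep(yrs, each = 12L),
    month = rep(1:12, times = n),
    temperature = as.vector(t(temp)),
    precipitation = as.vector(t(prec)),
    ao = as.vector(t(ao))
  )
  structure(out, class = c("climate_table", "data.frame"))
}

#' Aggregate a monthly climate table into an annual series
#'
#' @param climate a \code{climate_table}.
#' @param variable one of \code{"temperature"}, \code{"precipitation"},
#'   \code{"ao"}.
#' @param months months to aggregate over (e.g. \code{7} for July,
#'   \code{6:8} for JJA).
#' @param fun aggregation function name: \code{"mean"} or \code{"sum"}.
#'   Defaults to \code{"sum"} for precipitation (monthly totals add) and
#'   \code{"mean"} otherwise.
#' @return an \code{annual_series}.
#' @export
climate_aggregate <- function(climate,
                              variable = c("temperature", "precipitation", "ao"),
                              months = 7L, fun = NULL) {
  variable <- match.arg(variable)
  if (is.null(fun)) fun <- if (variable == "precipitation") "sum" else "mean"
  fun <- match.arg(fun, c("mean", "sum"))
  sub <- climate[climate$month %in% months, c("year", variable)]
  agg <- tapply(sub[[variable]], sub$year, if (fun == "sum") sum else mean)
  annual_series(as.integer(names(agg)), as.numeric(agg))
}

#' Generate a synthetic atmospheric d13C record
#'
#' Constant at the pre-industrial value up to the reference year, then a
#' smooth quadratic-in-time decline reaching \code{pre_industrial - decline}
#' per mil at \code{end_year} (the Suess effect imprinted by fossil-fuel
#' CO2).  Years beyond \code{end_year} continue on the same quadratic.
#'
#' @param years year range or vector (calendar years CE).
#' @param pre_industrial the plateau value, per mil VPDB.
#' @param decline total decline from the plateau at \code{end_year}, per mil.
#' @param ref_year last plateau year (default 1850).
#' @param end_year year at which the full decline is reached.
#' @return data frame of class \code{atm_record} with columns \code{year},
#'   \code{d13c_atm}.
#' @examples
#' atm <- gen_atm_record(c(1800, 2009))
#' atm$d13c_atm[atm$year == 1850]  # -6.4
#' @export
gen_atm_record <- function(years, pre_industrial = -6.4, decline = 2,
                           ref_year = 1850L, end_year = 2009L) {
  yrs <- period_years(years)
  if (is.null(yrs) || length(yrs) == 0L)
    stop_dendroiso("empty year range", "invalid_argument")
  frac <- pmax(0, (yrs - ref_year) / (end_year - ref_year))
  d13 <- pre_industrial - decline * frac^2
  structure(data.frame(year = yrs, d13c_atm = d13),
            class = c("atm_record", "data.frame"))
}

# Look up the Suess term atm(t) - atm(ref_year); zero before ref_year.
# Hard error on missing coverage -- no silent interpolation.
suess_term <- function(years, atm, ref_year = 1850L) {
  ref_idx <- match(ref_year, atm$year)
  need <- years[years >= ref_year]
  if (length(need)) {
    if (is.na(ref_idx))
      stop_dendroiso("atmospheric record does not cover the reference year",
                     "coverage")
    if (!all(need %in% atm$year))
      stop_dendroiso("atmospheric record missing years needed for the Suess term",
                     "coverage")
  }
  delta <- numeric(length(years))
  post <- years >= ref_year
  if (any(post))
    delta[post] <- atm$d13c_atm[match(years[post], atm$year)] - atm$d13c_atm[ref_idx]
  delta
}

# Place n trees over [y0, yend]: the first `min_replication` trees are
# anchored at the range start, a "living" fraction ends at the range end
# (mirroring living-tree cores), the rest are staggered.  A greedy repair
# pass then guarantees that every year from y0 + juvenile_length to yend is
# covered by at least `min_replication` trees even after juvenile trimming.
place_trees <- function(n, y0, yend, lifespan_mean, lifespan_sd, min_lifespan,
                        living_fraction, min_replication, juvenile_length,
                        seed) {
  span <- yend - y0 + 1L
  if (min_lifespan > span)
    stop_dendroiso("year range shorter than the minimum lifespan", "invalid_argument")
  n_anchor <- min(min_replication, n)
  n_living <- min(max(0L, round(living_fraction * n)), n - n_anchor)
  n_mid <- n - n_anchor - n_living

  L <- integer(n); s <- integer(n)
  for (i in seq_len(n)) {
    set.seed(tree_seed(seed, i))
    Li <- round(stats::rnorm(1, lifespan_mean, lifespan_sd))
    Li <- max(min_lifespan, min(Li, span))
    jit <- round(stats::rnorm(1, 0, 25))
    if (i <= n_anchor) {
      si <- y0
    } else if (i > n - n_living) {
      si <- yend - Li + 1L
    } else {
      k <- i - n_anchor
      target_end <- max(y0, yend - lifespan_mean)
      si <- y0 + round(k * (target_end - y0) / (n_mid + 1)) + jit
      si <- max(y0, min(si, yend - Li + 1L))
    }
    L[i] <- as.integer(Li); s[i] <- as.integer(si)
  }
  e <- pmin(s + L - 1L, yend)

  # greedy coverage repair on juvenile-trimmed intervals
  target <- (y0 + juvenile_length):yend
  for (iter in 1:10000) {
    cov <- integer(length(target))
    for (i in seq_len(n)) {
      lo <- max(s[i] + juvenile_length, target[1L])
      hi <- e[i]
      if (hi >= lo)
        cov[(lo - target[1L] + 1L):(hi - target[1L] + 1L)] <-
          cov[(lo - target[1L] + 1L):(hi - target[1L] + 1L)] + 1L
    }
    deficit <- target[cov < min_replication]
    if (!length(deficit)) break
    y <- deficit[1L]
    best_i <- NA_integer_; best_cost <- Inf; best_side <- ""
    for (i in seq_len(n)) {
      trim_start <- s[i] + juvenile_length
      if (trim_start <= y && y <= e[i]) next
      if (trim_start > y) {
        new_s <- y - juvenile_length
        if (new_s >= y0) {
          cost <- s[i] - new_s
          if (cost < best_cost) { best_cost <- cost; best_i <- i; best_side <- "start" }
        }
      } else if (e[i] < y) {
        cost <- y - e[i]
        if (cost < best_cost) { best_cost <- cost; best_i <- i; best_side <- "end" }
      }
    }
    if (is.na(best_i))
      stop_dendroiso(sprintf(
        "cannot tile %d trees over %d-%d with >= %d-tree coverage", n, y0, yend,
        min_replication), "invalid_argument")
    if (best_side == "start") s[best_i] <- y - juvenile_length else e[best_i] <- y
  }
  data.frame(start = s, end = e)
}

#' Generate synthetic per-tree isotope series
#'
#' Each tree's value in year t is
#' \code{intercept + tree_offset + slope * A(t) + juvenile(age) +
#' suess(t) + noise(t)}, where \code{A(t)} is a monthly climate aggregate
#' (the ground-truth climate driver), \code{tree_offset} is a fixed
#' N(0, tree_sd) effect per tree, \code{juvenile(age)} is a linear ramp of
#' magnitude \code{juvenile_amplitude} decaying to zero at ring age
#' \code{juvenile_length}, \code{suess(t) = atm(t) - atm(1850)} when an
#' atmospheric record is supplied (carbon only), and \code{noise} is iid
#' N(0, noise_sd) measurement error (analytical precision ~0.2 per mil).
#'
#' Tree lifespans are drawn from a clipped normal (mean
#' \code{lifespan_mean}) and staggered so that every year of the range is
#' covered by at least \code{min_replication} trees, including after the
#' first \code{juvenile_length} rings are trimmed from year
#' \code{start + juvenile_length} onwards.  Random draws for each tree come
#' from a per-tree substream of \code{seed}.
#'
#' @param climate a \code{climate_table} covering the full tree span.
#' @param n_trees number of trees (>= 1).
#' @param target the climate driver: a list with \code{variable},
#'   \code{months} and optionally \code{fun}, passed to
#'   \code{\link{climate_aggregate}}.  Default: July precipitation.
#' @param slope,intercept affine map from the climate aggregate to the
#'   isotope value (per mil per climate unit; per mil).  Defaults emulate a
#'   d13C/July-precipitation coupling (slope -1/16.723).
#' @param tree_sd SD of the fixed between-tree offsets, per mil.
#' @param noise_sd SD of the iid measurement noise, per mil.
#' @param juvenile_amplitude value of the juvenile trend at ring age 0,
#'   per mil (often negative for canopy-effect depletion).
#' @param juvenile_length ring age at which the juvenile trend reaches zero.
#' @param lifespan_mean,lifespan_sd,min_lifespan lifespan distribution, years.
#' @param living_fraction fraction of trees whose series end at the final
#'   year (living trees at sampling).
#' @param min_replication minimum tree coverage guaranteed everywhere.
#' @param atm optional \code{atm_record} used to imprint the Suess decline
#'   (applies when \code{scale = "d13C"}).
#' @param scale isotope scale tag, \code{"d13C"} or \code{"d18O"}.
#' @param seed integer seed.
#' @return a list of \code{\link{tree_series}} objects with a \code{truth}
#'   attribute recording every generator parameter (including per-tree
#'   offsets and placements) for recovery tests.
#' @export
gen_tree_series <- function(climate, n_trees = 42L,
                            target = list(variable = "precipitation", months = 7L),
                            slope = -1 / 16.723, intercept = -21.43,
                            tree_sd = 0.3, noise_sd = 0.2,
                            juvenile_amplitude = -0.5, juvenile_length = 50L,
                            lifespan_mean = 300, lifespan_sd = 60,
                            min_lifespan = 180L, living_fraction = 20 / 42,
                            min_replication = 4L, atm = NULL,
                            scale = c("d13C", "d18O"), seed = 1L) {
  scale <- match.arg(scale)
  if (n_trees < 1) stop_dendroiso("n_trees must be >= 1", "invalid_argument")
  agg <- do.call(climate_aggregate, c(list(climate = climate), target))
  y0 <- min(agg$year); yend <- max(agg$year)
  pl <- place_trees(n_trees, y0, yend, lifespan_mean, lifespan_sd, min_lifespan,
                    living_fraction, min_replication, juvenile_length, seed)
  agg_val <- agg$value[match(y0:yend, agg$year)]

  trees <- vector("list", n_trees)
  offsets <- numeric(n_trees)
  for (i in seq_len(n_trees)) {
    yrs_i <- pl$start[i]:pl$end[i]
    set.seed(tree_seed(seed, i) + 1L)
    offsets[i] <- stats::rnorm(1, 0, tree_sd)
    noise <- stats::rnorm(length(yrs_i), 0, noise_sd)
    age <- yrs_i - pl$start[i]
    juv <- juvenile_amplitude * pmax(0, 1 - age / juvenile_length)
    su <- if (!is.null(atm) && scale == "d13C") suess_term(yrs_i, atm) else 0
    vals <- intercept + offsets[i] + slope * agg_val[yrs_i - y0 + 1L] +
      juv + su + noise
    trees[[i]] <- tree_series(sprintf("T%02d", i), pl$start[i], vals,
                              pith_year = pl$start[i], scale = scale)
  }
  attr(trees, "truth") <- list(
    slope = slope, intercept = intercept, tree_sd = tree_sd,
    noise_sd = noise_sd, juvenile_amplitude = juvenile_amplitude,
    juvenile_length = juvenile_length, target = target,
    offsets = offsets, placements = pl, scale = scale, seed = seed
  )
  class(trees) <- c("tree_collection", "list")
  trees
}

#' Generate a complete synthetic dataset
#'
#' Bundles a climate table, an atmospheric d13C record, a carbon-isotope
#' tree set driven by July precipitation (with the Suess decline imprinted)
#' and an oxygen-isotope tree set driven by the May AO index, with all
#' ground-truth parameters recorded.  This is the stand-in for a real
#' archived isotope dataset and defines the default study conditions of the
#' pipeline: 42 trees over 466-2009 CE, 0.2 per-mil measurement noise, and
#' a d13C/July-precipitation slope of -1/16.723 per mil per mm.
#'
#' @param years year range (default \code{c(466, 2009)}; the first 50 years
#'   feed the juvenile trim so the chronology proper starts at 516).
#' @param seed integer seed; fans out to climate and per-tree substreams.
#' @param climate_args,d13c_args,d18o_args named lists overriding
#'   \code{\link{gen_climate}} / \code{\link{gen_tree_series}} defaults.
#' @param volcanic_catalog eruption catalog forcing the climate (default:
#'   the packaged catalog, \code{\link{eruption_catalog}}).
#' @return a list with elements \code{climate}, \code{atm},
#'   \code{trees_d13c}, \code{trees_d18o}, \code{volcanic}, \code{truth}.
#' @export
gen_dataset <- function(years = c(466L, 2009L), seed = 1L,
                        climate_args = list(), d13c_args = list(),
                        d18o_args = list(),
                        volcanic_catalog = eruption_catalog()) {
  seed <- as.integer(seed)
  climate <- do.call(gen_climate,
                     c(list(years = years, seed = seed,
                            volcanic_catalog = volcanic_catalog),
                       climate_args))
  atm <- gen_atm_record(years)
  trees_d13c <- do.call(gen_tree_series,
                        c(list(climate = climate, atm = atm, scale = "d13C",
                               seed = seed + 1000L),
                          d13c_args))
  d18o_defaults <- list(target = list(variable = "ao", months = 5L),
                        slope = 1 / 0.320, intercept = 22.11,
                        tree_sd = 0.4, scale = "d18O",
                        seed = seed + 2000L)
  d18o_defaults[names(d18o_args)] <- d18o_args
  trees_d18o <- do.call(gen_tree_series, c(list(climate = climate), d18o_defaults))
  list(climate = climate, atm = atm,
       trees_d13c = trees_d13c, trees_d18o = trees_d18o,
       volcanic = volcanic_catalog,
       truth = list(seed = seed,
                    d13c = attr(trees_d13c, "truth"),
                    d18o = attr(trees_d18o, "truth")))
}
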