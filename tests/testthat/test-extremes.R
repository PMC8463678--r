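# Hamming smoothing, sigma-threshold extremes, period contrasts, and
# volcanic matching.

test_that("Hamming weights match the defining formula", {
  w3 <- hamming_weights(3)
  raw <- c(0.08, 1.0, 0.08)
  expect_equal(w3, raw / sum(raw), tolerance = 1e-12)
  w41 <- hamming_weights(41)
  k <- 0:40
  expect_equal(w41, (0.54 - 0.46 * cos(2 * pi * k / 40)) /
                 sum(0.54 - 0.46 * cos(2 * pi * k / 40)), tolerance = 1e-12)
  expect_equal(sum(w41), 1)
  expect_error(hamming_weights(4), class = "dendroiso_invalid_argument")
})

test_that("Hamming weights agree with the signal package's window", {
  skip_if_not_installed("signal")
  w <- hamming_weights(41)
  ref <- as.numeric(signal::hamming(41))
  expect_equal(w, ref / sum(ref), tolerance = 1e-12)
})

test_that("smoothing preserves constants, bounds, and the impulse response", {
  const <- annual_series(1900:2000, rep(2.5, 101))
  expect_equal(hamming_smooth(const, 41)$value, rep(2.5, 101))

  # unit impulse at the center: output there equals the central weight
  n <- 81
  imp <- numeric(n); imp[41] <- 1
  sm <- hamming_smooth(imp, 41)
  expect_equal(sm[41], hamming_weights(41)[21], tolerance = 1e-12)

  set.seed(12)
  x <- annual_series(516:2009, rnorm(1494))
  s <- hamming_smooth(x, 101)
  expect_true(all(s$value >= min(x$value) & s$value <= max(x$value)))
  expect_equal(s$year, x$year)

  expect_error(hamming_smooth(x, 40), class = "dendroiso_invalid_argument")
  expect_error(hamming_smooth(annual_series(1:5, 1:5), 7),
               class = "dendroiso_invalid_argument")
  gappy <- annual_series(c(1:10, 12:20), rnorm(19))
  expect_error(hamming_smooth(gappy, 3), class = "dendroiso_invalid_argument")
})

test_that("extreme detection brackets thresholds correctly", {
  set.seed(41)
  base <- rnorm(200)
  base <- (base - mean(base)) / sd(base)  # mean 0, SD 1 exactly
  s <- annual_series(1801:2000, base)
  s$value[50] <- 2.5   # between 2 and 3 sigma (SD barely changes)
  ex <- detect_extremes(annual_series(s$year, s$value),
                        reference_period = NULL)
  row <- ex[ex$year == 1850, ]
  expect_equal(nrow(row), 1)
  expect_equal(row$level, 2)
  expect_equal(row$sign, "positive")

  # a value beyond -3 sigma is annotated at the 3 sigma level
  d <- 0.8 / sqrt(2)
  s2 <- annual_series(1:3, c(-24.9 - d, -24.9 + d, -24.9 - 3.2 * 0.8))
  ex2 <- detect_extremes(s2, reference_period = c(1, 2))
  expect_equal(ex2$year, 3L)
  expect_equal(ex2$level, 3)
  expect_equal(ex2$sign, "negative")

  quiet <- annual_series(1:100, sin(seq(0, 6, length.out = 100)))
  expect_equal(nrow(detect_extremes(quiet)), 0)
  expect_error(detect_extremes(annual_series(1:5, rep(1, 5))),
               class = "dendroiso_degenerate")
})

test_that("extreme detection is invariant under affine rescaling", {
  set.seed(3)
  s <- annual_series(1:300, rnorm(300))
  a <- detect_extremes(s)
  b <- detect_extremes(annual_series(s$year, 7 - 3 * s$value))
  expect_equal(a$year, b$year)
  expect_equal(a$z, -b$z, tolerance = 1e-10)  # negative scale flips sign
  expect_equal(a$level, b$level)
})

test_that("period_contrast recovers means and trends", {
  flat <- annual_series(1:100, rep(5, 100))
  pc <- period_contrast(flat, c(1, 50), c(51, 100))
  expect_equal(pc$difference, 0)
  expect_equal(pc$trend_a$r2, 0)

  line <- annual_series(1:100, as.numeric(1:100))
  pl <- period_contrast(line, c(1, 50), c(51, 100))
  expect_equal(pl$trend_a$r2, 1)
  expect_equal(pl$trend_b$r2, 1)

  # imposed step change is recovered within 2 SE
  set.seed(9)
  vals <- c(rnorm(284, 60.4, 5), rnorm(210, 44.3, 5))
  stepped <- annual_series(1516:2009, vals)
  ps <- period_contrast(stepped, c(1516, 1799), c(1800, 2009))
  se <- sqrt(25 / 284 + 25 / 210)
  expect_lt(abs(ps$difference - (44.3 - 60.4)), 2 * se)
  expect_error(period_contrast(flat, c(200, 300), c(51, 100)),
               class = "dendroiso_coverage")
})

test_that("volcanic matching respects VEI cutoff and lag window", {
  cat <- data.frame(year = c(1815, 1883), name = c("Tambora", "Krakatoa"),
                    vei = c(7, 6))
  ex <- data.frame(year = c(1815, 1816), z = c(-2.5, -2.2),
                   sign = "negative", level = c(2, 2))
  m <- match_volcanic(ex, cat, lag_window = c(0, 3))
  expect_equal(m$n_matched[m$year == 1815], 2L)
  expect_equal(attr(m, "matched_extreme_years"), c(1815L, 1816L))
  expect_equal(attr(m, "n_unmatched_eruptions"), 1L)

  # zero-width lag window excludes the year after
  m0 <- match_volcanic(data.frame(year = 1816), cat, lag_window = c(0, 0))
  expect_equal(sum(m0$n_matched), 0L)

  # empty extremes give zero matches
  me <- match_volcanic(data.frame(year = integer()), cat)
  expect_true(all(me$n_matched == 0))

  # VEI filter removes small eruptions
  small <- data.frame(year = 1900, name = "minor", vei = 3)
  expect_equal(nrow(match_volcanic(ex, rbind(cat, small), min_vei = 4)), 2)
  expect_error(match_volcanic(ex, cat[0, ]),
               class = "dendroiso_invalid_argument")
})

test_that("volcanic match count is monotone in the lag-window width", {
  set.seed(15)
  cat <- data.frame(year = sort(sample(1000:1900, 10)),
                    name = letters[1:10], vei = (4:8)[sample.int(5, 10, TRUE)])
  ex <- data.frame(year = sort(sample(1000:1910, 60)))
  counts <- vapply(0:6, function(L)
    sum(match_volcanic(ex, cat, lag_window = c(0, L))$n_matched), 0)
  expect_true(all(diff(counts) >= 0))
})
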