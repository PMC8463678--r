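# Pseudoproxy generator: deterministic, correct in the noise-free limit,
# with the stated AR(1) structure, Suess decline, and coverage guarantees.

test_that("noise-free climate equals the monthly climatology exactly", {
  cl <- gen_climate(c(1900, 1950), ar1_coeff = 0, innovation_sd = 0,
                    precip_rel_sd = 0, ao_sd = 0, seed = 3)
  july <- cl[cl$month == 7, ]
  expect_equal(july$temperature, rep(12.6, nrow(july)))
  expect_equal(july$precipitation, rep(58, nrow(july)))
  expect_true(all(cl$ao == 0))
  expect_equal(sum(cl$precipitation[cl$year == 1920]), 280)
})

test_that("the generator is deterministic under a fixed seed", {
  a <- gen_climate(c(1800, 1900), seed = 11)
  b <- gen_climate(c(1800, 1900), seed = 11)
  expect_identical(a, b)
  ta <- gen_tree_series(a, n_trees = 6, seed = 5, min_lifespan = 80,
                        lifespan_mean = 101, min_replication = 4)
  tb <- gen_tree_series(b, n_trees = 6, seed = 5, min_lifespan = 80,
                        lifespan_mean = 101, min_replication = 4)
  expect_identical(ta, tb)
  expect_false(identical(a, gen_climate(c(1800, 1900), seed = 12)))
})

test_that("July temperature has the requested lag-1 autocorrelation", {
  cl <- gen_climate(c(1, 10000), ar1_coeff = 0.5, innovation_sd = 1, seed = 42)
  july <- cl$temperature[cl$month == 7]
  acf1 <- stats::acf(july, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(acf1 - 0.5), 0.05)
})

test_that("eruption years depress temperature in year 0 and +1", {
  cat <- data.frame(year = 1500, name = "test", vei = 6)
  quiet <- gen_climate(c(1490, 1510), ar1_coeff = 0, innovation_sd = 0,
                       precip_rel_sd = 0, ao_sd = 0, seed = 1)
  forced <- gen_climate(c(1490, 1510), ar1_coeff = 0, innovation_sd = 0,
                        precip_rel_sd = 0, ao_sd = 0, seed = 1,
                        volcanic_catalog = cat, volcanic_cooling = 2,
                        volcanic_ao_shift = -1)
  dT <- climate_aggregate(forced, "temperature", 7)$value -
        climate_aggregate(quiet, "temperature", 7)$value
  yrs <- climate_aggregate(forced, "temperature", 7)$year
  expect_equal(dT[yrs %in% c(1500, 1501)], c(-2, -2))
  expect_true(all(dT[!(yrs %in% c(1500, 1501))] == 0))
  dA <- climate_aggregate(forced, "ao", 5)$value
  expect_equal(dA[yrs == 1500], -1)
})

test_that("gen_climate rejects empty ranges and bad AR coefficients", {
  expect_error(gen_climate(integer(0)), class = "dendroiso_invalid_argument")
  expect_error(gen_climate(c(1900, 1950), ar1_coeff = 1),
               class = "dendroiso_invalid_argument")
})

test_that("atmospheric record: plateau, reference year, and Suess decline", {
  atm <- gen_atm_record(c(1700, 2009))
  expect_equal(atm$d13c_atm[atm$year == 1850], -6.4)
  expect_true(all(atm$d13c_atm[atm$year < 1850] == -6.4))
  expect_lt(atm$d13c_atm[atm$year == 2009] - atm$d13c_atm[atm$year == 1850], 0)
  expect_equal(atm$d13c_atm[atm$year == 2009], -8.4)
  post <- atm$d13c_atm[atm$year >= 1850]
  expect_true(all(diff(post) <= 0))  # monotone decline
})

test_that("noise-free trees are an exact affine map of the climate aggregate", {
  fx <- noise_free_dataset()
  agg_map <- setNames(fx$agg$value, fx$agg$year)
  for (tr in fx$trees) {
    expected <- fx$intercept + fx$slope * unname(agg_map[as.character(tr$years)])
    expect_equal(tr$values, expected, tolerance = 1e-12)
  }
})

test_that("42 trees over 516-2009 cover every year with >= 4 trees", {
  cl <- gen_climate(c(516, 2009), seed = 2)
  trees <- gen_tree_series(cl, n_trees = 42, seed = 2)
  depth <- table(factor(unlist(lapply(trees, function(t) t$years)),
                        levels = 516:2009))
  expect_true(all(depth >= 4))
  # and >= 4 even after the juvenile trim, from year start+50 onwards
  trimmed <- lapply(trees, trim_juvenile, n_exclude = 50)
  depth_tr <- table(factor(unlist(lapply(trimmed, function(t) t$years)),
                           levels = 566:2009))
  expect_true(all(depth_tr >= 4))
})

test_that("post-1850 synthetic d13C decline is removed by the Suess correction", {
  years <- c(1800, 2009)
  cl <- gen_climate(years, ar1_coeff = 0, innovation_sd = 0,
                    precip_rel_sd = 0, ao_sd = 0, seed = 1)
  atm <- gen_atm_record(years)
  trees <- gen_tree_series(cl, n_trees = 4, slope = -0.06, intercept = -21.4,
                           tree_sd = 0, noise_sd = 0, juvenile_amplitude = 0,
                           lifespan_mean = 300, min_lifespan = 210,
                           min_replication = 4, atm = atm, seed = 1)
  chron <- build_chronology(lapply(trees, trim_juvenile))
  # raw chronology declines with the atmosphere; corrected one is flat
  expect_lt(chron$mean[chron$year == 2009], chron$mean[chron$year == 1850])
  corr <- correct_suess(chron, atm)$corrected
  expect_equal(stats::sd(corr$mean), 0, tolerance = 1e-12)
  trend <- stats::coef(stats::lm(mean ~ year, data = as.data.frame(corr)))[2]
  expect_equal(unname(trend), 0, tolerance = 1e-12)
})

test_that("infeasible tiling is rejected", {
  cl <- gen_climate(c(1900, 1950), seed = 1)
  expect_error(gen_tree_series(cl, n_trees = 2, min_replication = 4,
                               min_lifespan = 30, lifespan_mean = 40),
               class = "dendroiso_invalid_argument")
})
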