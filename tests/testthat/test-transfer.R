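# Transfer functions: OLS against the normal equations, the published
# equation fixtures, verification statistics against brute-force oracles
# and independent implementations, and the split-calibration report.

test_that("an exact line is recovered with zero residual", {
  x <- annual_series(2000:2009, 1:10)
  y <- annual_series(2000:2009, 2 * (1:10) + 1)
  m <- fit_transfer(x, y)
  expect_equal(unname(m$slope), 2)
  expect_equal(m$intercept, 1)
  expect_equal(m$residual_rmse, 0, tolerance = 1e-10)
  expect_equal(m$r2, 1)
})

test_that("OLS coefficients equal the closed-form normal-equation solution", {
  px <- c(1.2, 2.1, 2.9, 4.3, 5.0)
  py <- c(2.0, 4.4, 5.9, 8.9, 10.1)
  m <- fit_transfer(annual_series(1:5, px), annual_series(1:5, py))
  X <- cbind(1, px)
  beta <- solve(t(X) %*% X, t(X) %*% py)  # brute-force oracle
  expect_equal(m$intercept, beta[1], tolerance = 1e-12)
  expect_equal(unname(m$slope), beta[2], tolerance = 1e-12)
})

test_that("fit_transfer rejects degenerate inputs", {
  expect_error(fit_transfer(annual_series(1:2, 1:2), annual_series(1:2, 1:2)),
               class = "dendroiso_invalid_argument")
  expect_error(fit_transfer(annual_series(1:5, rep(1, 5)),
                            annual_series(1:5, rnorm(5))),
               class = "dendroiso_degenerate_fit")
})

test_that("the published transfer equations evaluate as printed", {
  mods <- taimyr_models()
  p <- apply_transfer(mods$july_precip_d13c, annual_series(2000, -24.0))
  expect_equal(p$value, -357.791 + (-16.723) * (-24.0) + 0.15)
  expect_equal(p$value, 43.711)
  a <- apply_transfer(mods$ao_may_d18o, annual_series(2000, 21.640625))
  expect_equal(a$value, 0)
  # fixture models carry no residual estimate -> no CI band
  expect_true(is.na(p$lower) && is.na(p$upper))
})

test_that("apply_transfer reproduces OLS fitted values and handles edge cases", {
  set.seed(10)
  x <- annual_series(1950:2009, rnorm(60, -24, 0.8))
  y <- annual_series(1950:2009, 50 - 16 * (x$value + 24) + rnorm(60, 0, 5))
  m <- fit_transfer(x, y, c(1950, 2009))
  rec <- apply_transfer(m, x)
  fit <- stats::lm(y$value ~ x$value)
  expect_equal(rec$value, unname(stats::fitted(fit)), tolerance = 1e-10)
  expect_equal(rec$upper - rec$value, rep(1.96 * m$residual_rmse, 60))

  flat <- transfer_model(slope = 0, intercept = 3, extra_offset = 0.5)
  expect_equal(apply_transfer(flat, x)$value, rep(3.5, 60))
})

test_that("verification statistics hit their defining anchors", {
  set.seed(5)
  obs <- rnorm(30)
  # perfect reconstruction
  s <- skill_stats(obs, obs, calibration_mean = 0.3)
  expect_equal(s$r, 1); expect_equal(s$RE, 1); expect_equal(s$CE, 1)
  expect_equal(s$Ks, 1)
  # the calibration-mean forecast has RE = 0 by definition
  s0 <- skill_stats(obs, rep(0.3, 30), calibration_mean = 0.3)
  expect_equal(s0$RE, 0)
  # alternating residuals drive DW towards 4
  n <- 10000
  obs2 <- rnorm(n)
  rec2 <- obs2 - rep(c(1, -1), n / 2)
  expect_lt(abs(skill_stats(obs2, rec2, 0)$DW - 4), 0.01)
})

test_that("RE/CE/DW/Ks match brute-force oracles on random series", {
  set.seed(123)
  for (i in 1:50) {
    n <- sample(5:50, 1)
    obs <- rnorm(n); rec <- rnorm(n); cm <- rnorm(1)
    s <- skill_stats(obs, rec, cm)
    sse <- 0; for (t in 1:n) sse <- sse + (obs[t] - rec[t])^2
    den_re <- 0; for (t in 1:n) den_re <- den_re + (obs[t] - cm)^2
    den_ce <- 0; for (t in 1:n) den_ce <- den_ce + (obs[t] - mean(obs))^2
    e <- obs - rec
    num_dw <- 0; for (t in 2:n) num_dw <- num_dw + (e[t] - e[t - 1])^2
    ks <- 0
    for (t in 2:n) {
      d1 <- obs[t] - obs[t - 1]; d2 <- rec[t] - rec[t - 1]
      ks <- ks + if (d1 == 0 || d2 == 0) 0.5 else as.numeric(sign(d1) == sign(d2))
    }
    expect_equal(s$RE, 1 - sse / den_re, tolerance = 1e-12)
    expect_equal(s$CE, 1 - sse / den_ce, tolerance = 1e-12)
    expect_equal(s$DW, num_dw / sum(e^2), tolerance = 1e-12)
    expect_equal(s$Ks, ks / (n - 1), tolerance = 1e-12)
  }
})

test_that("DW agrees with the independent lmtest implementation", {
  skip_if_not_installed("lmtest")
  set.seed(21)
  x <- rnorm(40); y <- 2 * x + rnorm(40)
  fit <- stats::lm(y ~ x)
  e <- stats::resid(fit)
  dw_pkg <- unname(lmtest::dwtest(fit)$statistic)
  ours <- skill_stats(y, y - e, calibration_mean = mean(y))$DW
  expect_equal(ours, dw_pkg, tolerance = 1e-10)
})

test_that("CE <= RE always, and both are shift-invariant", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(5:50, 1)
    obs <- rnorm(n); rec <- rnorm(n); cm <- rnorm(1)
    s <- skill_stats(obs, rec, cm)
    expect_lte(s$CE, s$RE + 1e-12)
    sh <- skill_stats(obs + 3.7, rec + 3.7, cm + 3.7)
    expect_equal(sh$RE, s$RE, tolerance = 1e-10)
    expect_equal(sh$CE, s$CE, tolerance = 1e-10)
  }
})

test_that("verify enforces disjoint periods and scores the right window", {
  set.seed(31)
  proxy <- annual_series(1960:2009, rnorm(50, -24, 0.8))
  target <- annual_series(1960:2009, 58 - 16 * (proxy$value + 24) + rnorm(50, 0, 4))
  m <- fit_transfer(proxy, target, c(1990, 2009))
  expect_error(verify(m, proxy, target, c(1985, 1995)),
               class = "dendroiso_invalid_split")
  v <- verify(m, proxy, target, c(1960, 1989))
  expect_equal(v$n, 30)
  expect_true(v$RE > 0 && v$CE <= v$RE)
})

test_that("calibrate_full reports both directions and bootstrap percentiles", {
  set.seed(8)
  proxy <- annual_series(1969:2009, rnorm(41, -24, 0.8))
  target <- annual_series(1969:2009,
                          58 - 16 * (proxy$value + 24) + rnorm(41, 0, 3))
  rep <- calibrate_full(proxy, target, c(1990, 2009), c(1969, 1989),
                        n_boot = 300, seed = 2)
  expect_s3_class(rep$forward$stats, "verification_stats")
  expect_s3_class(rep$reverse$stats, "verification_stats")
  expect_equal(rep$final$n, 41)
  ci <- rep$coef_ci
  expect_true(ci[1, "proxy"] <= rep$final$slope && rep$final$slope <= ci[2, "proxy"])
  expect_error(calibrate_full(proxy, target, c(1990, 2009), c(1980, 1995)),
               class = "dendroiso_invalid_split")

  # noise-free: both directions identical, percentile band collapses
  t2 <- annual_series(1969:2009, 5 - 2 * proxy$value)
  r2 <- calibrate_full(proxy, t2, c(1990, 2009), c(1969, 1989),
                       n_boot = 100, seed = 1)
  expect_equal(unname(r2$forward$model$slope), unname(r2$reverse$model$slope),
               tolerance = 1e-9)
  expect_lt(diff(r2$coef_ci[, "proxy"]), 1e-9)
})

test_that("a multi-proxy fit matches lm and predicts consistently", {
  set.seed(14)
  a <- annual_series(1970:2009, rnorm(40))
  b <- annual_series(1970:2009, rnorm(40))
  y <- annual_series(1970:2009, 1 + 2 * a$value - 3 * b$value + rnorm(40, 0, 0.1))
  m <- fit_transfer(list(a = a, b = b), y)
  ref <- stats::lm(y$value ~ a$value + b$value)
  expect_equal(unname(m$slope), unname(stats::coef(ref)[2:3]), tolerance = 1e-10)
  rec <- apply_transfer(m, list(a = a, b = b))
  expect_equal(rec$value, unname(stats::fitted(ref)), tolerance = 1e-10)
})

test_that("correlation screening flags the true driver month", {
  cl <- gen_climate(c(1960, 2009), seed = 6)
  july <- climate_aggregate(cl, "precipitation", 7)
  set.seed(6)
  proxy <- annual_series(july$year, -21.4 - 0.06 * july$value + rnorm(50, 0, 0.1))
  ct <- correlate_monthly(proxy, cl)
  prec <- ct[ct$variable == "precipitation" & ct$predictor %in% as.character(1:12), ]
  expect_equal(prec$predictor[which.max(abs(prec$r))], "7")
  expect_lt(prec$p[prec$predictor == "7"], 0.001)
  expect_true(all(abs(ct$r) <= 1))
  expect_true(all(ct$n == 50))
  # perfect (anti-)correlation anchors
  ident <- correlate_monthly(annual_series(july$year, july$value), cl)
  expect_equal(ident$r[ident$variable == "precipitation" &
                         ident$predictor == "7"], 1)
  neg <- correlate_monthly(annual_series(july$year, -july$value), cl)
  expect_equal(neg$r[neg$variable == "precipitation" &
                       neg$predictor == "7"], -1)
  expect_error(correlate_monthly(annual_series(2001:2005, rnorm(5)), cl),
               class = "dendroiso_coverage")
})
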