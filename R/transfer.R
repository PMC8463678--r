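# Transfer functions: monthly correlation screening, inverse-calibration
# OLS (climate regressed on proxy), split-period calibration/verification
# with the dendroclimatological skill statistics, and reconstruction with
# a 95% confidence band.
#
# Skill statistics on a verification window with observations obs and
# reconstruction rec:
#   RE = 1 - SSE / sum((obs - calibration-period mean)^2)
#   CE = 1 - SSE / sum((obs - verification-period mean)^2)   (CE <= RE)
#   DW = sum(diff(e)^2) / sum(e^2)  on residuals e = obs - rec
#   Ks = fraction of adjacent year pairs whose first differences agree in
#        sign (Gleichlaeufigkeit), zero differences counting 1/2.

#' Screen monthly proxy-climate correlations
#'
#' Pearson correlation (with two-sided p via the t transform, as in
#' \code{stats::cor.test}) between a proxy series and every monthly climate
#' predictor plus seasonal aggregates, over the common period.
#'
#' @param proxy an annual proxy series (chronology or annual series).
#' @param climate a \code{climate_table}.
#' @param period optional period restriction (e.g. the instrumental era).
#' @param aggregates list of aggregate definitions, each a list with
#'   \code{label} and \code{months}.  Default: June-July, July-August,
#'   JJA, annual.
#' @param alpha significance level reported alongside (default 0.05).
#' @return data frame of class \code{correlation_table} with columns
#'   \code{variable}, \code{predictor}, \code{r}, \code{p}, \code{n}, and
#'   attribute \code{alpha}.
#' @export
correlate_monthly <- function(proxy, climate, period = NULL,
                              aggregates = list(
                                list(label = "Jun-Jul", months = 6:7),
                                list(label = "Jul-Aug", months = 7:8),
                                list(label = "JJA", months = 6:8),
                                list(label = "annual", months = 1:12)),
                              alpha = 0.05) {
  p <- series_window(as_annual_series(proxy), period)
  preds <- c(lapply(1:12, function(m) list(label = as.character(m), months = m)),
             aggregates)
  rows <- list()
  for (v in c("temperature", "precipitation", "ao")) {
    for (pr in preds) {
      cs <- climate_aggregate(climate, v, pr$months)
      d <- merge_series(p, cs)
      if (nrow(d) < 10L)
        stop_dendroiso(sprintf(
          "fewer than 10 overlapping years between proxy and %s (%s)",
          v, pr$label), "coverage")
      ct <- stats::cor.test(d$x, d$y)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, predictor = pr$label,
        r = unname(ct$estimate), p = ct$p.value, n = nrow(d))
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("correlation_table", "data.frame"), alpha = alpha)
}

# Assemble the regression frame year/y/x1..xk from a target series and one
# proxy or a named list of proxies.
transfer_frame <- function(proxy, climate_target, period = NULL) {
  if (is.data.frame(proxy) || inherits(proxy, "tree_series") || !is.list(proxy))
    proxy <- list(proxy = proxy)
  if (is.null(names(proxy)) || any(names(proxy) == ""))
    names(proxy) <- paste0("proxy", seq_along(proxy))
  y <- series_window(as_annual_series(climate_target), period)
  yrs <- y$year
  for (p in proxy) yrs <- intersect(yrs, as_annual_series(p)$year)
  yrs <- sort(yrs)
  d <- data.frame(year = yrs, y = y$value[match(yrs, y$year)])
  for (nm in names(proxy)) {
    ps <- as_annual_series(proxy[[nm]])
    d[[nm]] <- ps$value[match(yrs, ps$year)]
  }
  d
}

#' Fit a linear transfer function (inverse calibration)
#'
#' Ordinary least squares of the climate target on the proxy (or proxies)
#' over the calibration period: the climate variable is the dependent
#' variable, the isotope chronology the independent one.  Prediction is
#' \code{sum(slope * proxy) + intercept + extra_offset}; freshly fitted
#' models have \code{extra_offset = 0}.
#'
#' @param proxy an annual proxy series, or a named list of several for a
#'   multiple regression (the standard reconstruction path uses one).
#' @param climate_target the annual climate series to calibrate against.
#' @param calibration_period period spec; default uses all common years.
#' @return an object of class \code{transfer_model}: slopes (named),
#'   intercept, \code{extra_offset}, \code{residual_rmse} (df-adjusted
#'   residual standard error), \code{r}, \code{r2}, standard errors,
#'   \code{calibration_years} and the calibration-period observed mean
#'   (used by RE in \code{\link{verify}}).
#' @export
fit_transfer <- function(proxy, climate_target, calibration_period = NULL) {
  d <- transfer_frame(proxy, climate_target, calibration_period)
  k <- ncol(d) - 2L
  if (nrow(d) < 3L)
    stop_dendroiso("need at least 3 calibration years", "invalid_argument")
  X <- as.matrix(d[, -(1:2), drop = FALSE])
  if (any(apply(X, 2L, stats::var) == 0))
    stop_dendroiso("proxy has zero variance over the calibration period",
                   "degenerate_fit")
  fit <- stats::lm(d$y ~ X)
  cf <- stats::coef(fit)
  sm <- suppressWarnings(summary(fit))  # perfect fits warn harmlessly
  se <- sm$coefficients[, 2L]
  structure(list(
    slope = stats::setNames(unname(cf[-1L]), colnames(X)),
    intercept = unname(cf[1L]),
    extra_offset = 0,
    slope_se = stats::setNames(unname(se[-1L]), colnames(X)),
    intercept_se = unname(se[1L]),
    residual_rmse = sm$sigma,
    r = if (k == 1L) stats::cor(X[, 1L], d$y) else sqrt(sm$r.squared),
    r2 = sm$r.squared,
    n = nrow(d),
    calibration_years = d$year,
    cal_mean_obs = mean(d$y)
  ), class = "transfer_model")
}

# Construct a transfer model directly from known coefficients (used for
# published equation fixtures; residual_rmse unknown -> NA, so the CI band
# is omitted).
transfer_model <- function(slope, intercept, extra_offset = 0,
                           residual_rmse = NA_real_, label = NULL) {
  structure(list(slope = slope, intercept = intercept,
                 extra_offset = extra_offset,
                 slope_se = NA_real_, intercept_se = NA_real_,
                 residual_rmse = residual_rmse,
                 r = NA_real_, r2 = NA_real_, n = NA_integer_,
                 calibration_years = NULL, cal_mean_obs = NA_real_,
                 label = label),
            class = "transfer_model")
}

#' @export
print.transfer_model <- function(x, ...) {
  terms <- paste(sprintf("%+.4g*%s", x$slope,
                         if (is.null(names(x$slope))) "proxy" else names(x$slope)),
                 collapse = " ")
  cat(sprintf("Transfer model: y = %.4g %s %s\n", x$intercept, terms,
              if (x$extra_offset != 0) sprintf("%+.3g", x$extra_offset) else ""))
  if (!is.na(x$r2))
    cat(sprintf("  r = %.3f, r2 = %.3f, RMSE = %.3f, n = %d (%d-%d)\n",
                x$r, x$r2, x$residual_rmse, x$n,
                min(x$calibration_years), max(x$calibration_years)))
  invisible(x)
}

predict_transfer <- function(model, frame) {
  nm <- names(model$slope)
  if (is.null(nm)) nm <- names(frame)[!(names(frame) %in% c("year", "y"))][1L]
  v <- model$intercept + model$extra_offset
  for (i in seq_along(model$slope)) v <- v + model$slope[[i]] * frame[[nm[i]]]
  as.numeric(v)
}

#' Apply a transfer function to a proxy series
#'
#' \code{rec(t) = slope * proxy(t) + intercept + extra_offset}, with a
#' constant 95% confidence band \code{rec +/- 1.96 * residual_rmse} (NA
#' when the model carries no residual estimate, as for published-equation
#' fixtures).
#'
#' @param model a \code{transfer_model}.
#' @param proxy the proxy series (or named list matching a multi-proxy
#'   model) to reconstruct from.
#' @return a data frame of class \code{reconstruction} with columns
#'   \code{year}, \code{value}, \code{lower}, \code{upper}.
#' @export
apply_transfer <- function(model, proxy) {
  if (is.data.frame(proxy) || inherits(proxy, "tree_series") || !is.list(proxy))
    proxy <- list(proxy = proxy)
  if (is.null(names(proxy)) || any(names(proxy) == ""))
    names(proxy) <- paste0("proxy", seq_along(proxy))
  yrs <- NULL
  for (p in proxy) {
    py <- as_annual_series(p)$year
    yrs <- if (is.null(yrs)) py else intersect(yrs, py)
  }
  yrs <- sort(yrs)
  if (!length(yrs)) stop_dendroiso("proxy is empty", "invalid_argument")
  frame <- data.frame(year = yrs)
  for (nm in names(proxy)) {
    ps <- as_annual_series(proxy[[nm]])
    frame[[nm]] <- ps$value[match(yrs, ps$year)]
  }
  if (length(model$slope) > 1L && !identical(sort(names(model$slope)),
                                             sort(names(proxy))))
    stop_dendroiso("proxy names do not match the multi-proxy model",
                   "invalid_argument")
  if (length(model$slope) == 1L) names(frame)[2L] <- names(model$slope)[1L] %||% "proxy"
  val <- predict_transfer(model, frame)
  half <- 1.96 * model$residual_rmse
  structure(data.frame(year = yrs, value = val,
                       lower = val - half, upper = val + half),
            class = c("reconstruction", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
as_annual_series.reconstruction <- function(x, ...) annual_series(x$year, x$value)

#' Verification skill statistics
#'
#' Compares observed and reconstructed values directly: Pearson r, RE, CE,
#' Durbin-Watson on the residuals, and the sign-agreement coefficient Ks
#' (ties count 1/2).  RE benchmarks against the calibration-period observed
#' mean, CE against the verification-period mean, so CE <= RE always.
#'
#' @param obs,rec observed and reconstructed values on the same years, in
#'   year order.
#' @param calibration_mean the calibration-period observed mean (the
#'   no-skill reference forecast for RE).
#' @return list with \code{r}, \code{RE}, \code{CE}, \code{DW}, \code{Ks},
#'   \code{n}.
#' @export
skill_stats <- function(obs, rec, calibration_mean) {
  if (length(obs) != length(rec))
    stop_dendroiso("obs and rec must have equal length", "invalid_argument")
  n <- length(obs)
  if (n < 3L)
    stop_dendroiso("need at least 3 verification years", "invalid_argument")
  sse <- sum((obs - rec)^2)
  e <- obs - rec
  do <- diff(obs); dr <- diff(rec)
  agree <- ifelse(do == 0 | dr == 0, 0.5, as.numeric(sign(do) == sign(dr)))
  structure(list(
    r = suppressWarnings(stats::cor(obs, rec)),
    RE = 1 - sse / sum((obs - calibration_mean)^2),
    CE = 1 - sse / sum((obs - mean(obs))^2),
    DW = sum(diff(e)^2) / sum(e^2),
    Ks = mean(agree),
    n = n
  ), class = "verification_stats")
}

#' @export
print.verification_stats <- function(x, ...) {
  cat(sprintf("Verification (n = %d): r = %.3f, RE = %.3f, CE = %.3f, DW = %.2f, Ks = %.2f\n",
              x$n, x$r, x$RE, x$CE, x$DW, x$Ks))
  invisible(x)
}

#' Verify a transfer model on an independent period
#'
#' Reconstructs the verification window from the proxy and scores it
#' against observations with \code{\link{skill_stats}}.  The verification
#' period must be disjoint from the model's calibration years.
#'
#' @param model a fitted \code{transfer_model}.
#' @param proxy proxy series (or named list).
#' @param climate_target observed climate series.
#' @param verification_period period spec for the verification window.
#' @return a \code{verification_stats} object.
#' @export
verify <- function(model, proxy, climate_target, verification_period) {
  vy <- period_years(verification_period)
  if (!is.null(model$calibration_years) &&
      length(intersect(vy, model$calibration_years)))
    stop_dendroiso("verification period overlaps the calibration period",
                   "invalid_split")
  d <- transfer_frame(proxy, climate_target, vy)
  if (nrow(d) < 3L)
    stop_dendroiso("need at least 3 verification years", "invalid_argument")
  rec <- predict_transfer(model, d)
  skill_stats(d$y, rec, model$cal_mean_obs)
}

#' Full split-period calibration with verification and bootstrap CIs
#'
#' Fits on the calibration window and verifies on the verification window,
#' repeats with the roles swapped, then fits the final model on the union
#' of both windows and derives 2.5/97.5 coefficient percentiles by residual
#' bootstrap on the union fit.
#'
#' @param proxy proxy series (or named list).
#' @param climate_target observed climate series.
#' @param cal_period,ver_period disjoint period specs.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed seed for the bootstrap resampling.
#' @return list of class \code{calibration_report}: \code{forward} /
#'   \code{reverse} (each with \code{model} and \code{stats}),
#'   \code{final} (the union-period model), and \code{coef_ci}, a matrix of
#'   2.5/97.5 percentiles for intercept and slopes.
#' @export
calibrate_full <- function(proxy, climate_target, cal_period, ver_period,
                           n_boot = 1000L, seed = 1L) {
  cy <- period_years(cal_period)
  vy <- period_years(ver_period)
  if (length(intersect(cy, vy)))
    stop_dendroiso("calibration and verification periods overlap",
                   "invalid_split")
  m_fwd <- fit_transfer(proxy, climate_target, cy)
  v_fwd <- verify(m_fwd, proxy, climate_target, vy)
  m_rev <- fit_transfer(proxy, climate_target, vy)
  v_rev <- verify(m_rev, proxy, climate_target, cy)
  union_years <- sort(unique(c(cy, vy)))
  final <- fit_transfer(proxy, climate_target, union_years)

  d <- transfer_frame(proxy, climate_target, union_years)
  X <- cbind(1, as.matrix(d[, -(1:2), drop = FALSE]))
  fitted <- predict_transfer(final, d)
  res <- d$y - fitted
  set.seed(as.integer(seed))
  boot <- matrix(NA_real_, n_boot, ncol(X))
  for (b in seq_len(n_boot)) {
    yb <- fitted + sample(res, replace = TRUE)
    boot[b, ] <- stats::lm.fit(X, yb)$coefficients
  }
  ci <- apply(boot, 2L, stats::quantile, probs = c(0.025, 0.975))
  colnames(ci) <- c("intercept", names(final$slope))
  structure(list(forward = list(model = m_fwd, stats = v_fwd),
                 reverse = list(model = m_rev, stats = v_rev),
                 final = final, coef_ci = ci,
                 cal_period = range(cy), ver_period = range(vy)),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("Calibration %d-%d / verification %d-%d\n",
              x$cal_period[1], x$cal_period[2], x$ver_period[1], x$ver_period[2]))
  cat("Forward:  "); print(x$forward$stats)
  cat("Reverse:  "); print(x$reverse$stats)
  cat("Final model (union period):\n"); print(x$final)
  cat("Coefficient 2.5/97.5 percentiles (residual bootstrap):\n")
  print(round(x$coef_ci, 4))
  invisible(x)
}
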