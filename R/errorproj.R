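# Conditional forecast-error modelling and scenario-consistent future
# error generation: a weighted spline regression for the conditional mean,
# a Gamma GLM (log link) for the conditional variance with an annual
# trend, standardized-error pooling in 5 degree C temperature bins, and
# resampling-based reconstruction of future errors.

# natural-spline design for temperature with boundary knots at -15/35 deg C
# and internal knots every 5 deg C; linear extrapolation outside boundary
.temp_spline <- function(temp, boundary = c(-15, 35), step = 5) {
  splines::ns(temp, knots = seq(boundary[1] + step, boundary[2] - step, step),
              Boundary.knots = boundary)
}

.error_design <- function(temp, wfo, wfo_levels, year = NULL) {
  S <- .temp_spline(temp)
  colnames(S) <- paste0("s", seq_len(ncol(S)))
  W <- outer(wfo, wfo_levels, `==`) * 1
  colnames(W) <- paste0("wfo_", wfo_levels)
  X <- cbind(W, S)
  if (!is.null(year)) X <- cbind(X, year = year)
  X
}

#' Fit the conditional mean of forecast errors
#'
#' Weighted least squares of the (raw) forecast error on a natural cubic
#' spline of realized temperature (boundary knots -15 and 35 deg C,
#' internal knots every 5 deg C) plus WFO intercepts.
#'
#' @param records county-day records with `error`, `temp`, `wfo_id`.
#' @param weights per-record weights (base-year county population);
#'   default equal.
#' @return object of class `error_mean_model` storing coefficients and WFO
#'   levels; predictions via [predict_error_mean()].
#' @export
fit_error_mean <- function(records, weights = NULL) {
  rec <- as.data.table(records)
  w <- weights %||% rep(1, nrow(rec))
  if (all(rec$temp < -15) || all(rec$temp > 35))
    warning("temperature support entirely outside the knot range; ",
            "predictions are pure extrapolation")
  lv <- sort(unique(rec$wfo_id))
  X <- .error_design(rec$temp, rec$wfo_id, lv)
  fit <- lm.wfit(X, rec$error, w)
  out <- list(coef = ifelse(is.na(fit$coefficients), 0, fit$coefficients),
              wfo_levels = lv)
  class(out) <- "error_mean_model"
  out
}

#' Predict the conditional mean forecast error
#' @param model an `error_mean_model`.
#' @param temp,wfo vectors of temperature and WFO id.
#' @return predicted mean error (deg C).
#' @export
predict_error_mean <- function(model, temp, wfo) {
  X <- .error_design(temp, wfo, model$wfo_levels)
  as.numeric(X %*% model$coef)
}

#' Fit the conditional variance of forecast errors
#'
#' Gamma GLM with log link for the squared deviations (e - mu_hat)^2 on
#' the same temperature spline, WFO intercepts, and a linear calendar-year
#' trend delta (per-year change in log variance).  The log link keeps
#' predicted variances positive under any extrapolation and encodes
#' percentage-wise (rather than absolute) accuracy improvements across the
#' temperature range.
#'
#' @param records county-day records with `error`, `temp`, `wfo_id`, `date`.
#' @param mean_model the [fit_error_mean()] model fitted on the same
#'   records.
#' @param weights per-record weights; default equal.
#' @return object of class `error_variance_model` with `coef`, `delta`
#'   (the year coefficient), `delta_se`, `wfo_levels`, `year_end` (last
#'   sample year, where scenario trends take over).
#' @export
fit_error_variance <- function(records, mean_model, weights = NULL) {
  rec <- as.data.table(records)
  w <- weights %||% rep(1, nrow(rec))
  mu <- predict_error_mean(mean_model, rec$temp, rec$wfo_id)
  y <- (rec$error - mu)^2
  if (all(y < .Machine$double.eps))
    stop("all squared deviations are zero; variance model is degenerate")
  yr <- year(rec$date)
  X <- .error_design(rec$temp, rec$wfo_id, mean_model$wfo_levels, year = yr)
  keep <- y > 0
  # starting values from a log-scale least-squares fit
  start <- lm.wfit(X[keep, , drop = FALSE], log(y[keep]), w[keep])$coefficients
  start[is.na(start)] <- 0
  fit <- glm.fit(X[keep, , drop = FALSE], y[keep], weights = w[keep],
                 family = stats::Gamma(link = "log"), start = start)
  cf <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  # model-based SE for the year trend: Fisher information with Pearson
  # dispersion (for a log-link Gamma GLM the information is X' diag(w) X)
  Vd <- tryCatch({
    mu_hat <- fit$fitted.values
    phi <- sum(w[keep] * (y[keep] - mu_hat)^2 / mu_hat^2) /
      (sum(keep) - sum(!is.na(fit$coefficients)))
    B <- chol2inv(chol(crossprod(X[keep, , drop = FALSE] *
                                   sqrt(w[keep]))))
    sqrt(phi * diag(B)[length(cf)])
  }, error = function(e) NA_real_)
  out <- list(coef = cf, delta = unname(cf["year"]), delta_se = Vd,
              wfo_levels = mean_model$wfo_levels, year_end = max(yr))
  class(out) <- "error_variance_model"
  out
}

#' Predict the conditional SD of forecast errors
#'
#' For years beyond the last sample year, the in-sample trend applies up
#' to `year_end` and the (possibly scenario-adjusted) trend
#' `delta_override` applies thereafter; within sample the fitted trend is
#' used throughout.
#'
#' @param model an `error_variance_model`.
#' @param temp,wfo,year vectors.
#' @param delta_override per-year log-variance trend applied after
#'   `year_end` (default: the fitted `delta`).
#' @return predicted SD (deg C), strictly positive.
#' @export
predict_error_sd <- function(model, temp, wfo, year,
                             delta_override = NULL) {
  d2 <- delta_override %||% model$delta
  y_in <- pmin(year, model$year_end)
  X <- .error_design(temp, wfo, model$wfo_levels, year = y_in)
  logvar <- as.numeric(X %*% model$coef) + d2 * pmax(year - model$year_end, 0)
  sqrt(exp(logvar))
}

#' Standardize historical errors and pool them by temperature bin
#'
#' e_tilde = (e - mu_hat) / sigma_hat per county-day, pooled into half-open
#' 5 degree C bins \[5k, 5k+5) of realized temperature (end bins open).
#' The standardized pool preserves the conditional skewness and kurtosis
#' of the historical errors for resampling.
#'
#' @param records county-day records.
#' @param mean_model,var_model fitted conditional-moment models.
#' @return object of class `std_error_pool`: list of numeric vectors named
#'   by bin lower edge, plus `bin_width`.
#' @export
standardize_errors <- function(records, mean_model, var_model) {
  rec <- as.data.table(records)
  mu <- predict_error_mean(mean_model, rec$temp, rec$wfo_id)
  sdv <- predict_error_sd(var_model, rec$temp, rec$wfo_id, year(rec$date))
  z <- (rec$error - mu) / sdv
  bin <- 5 * floor(rec$temp / 5)
  pool <- split(z, bin)
  out <- list(bins = pool,
              edges = sort(as.numeric(names(pool))),
              bin_width = 5)
  class(out) <- "std_error_pool"
  out
}

# nearest nonempty bin lookup for out-of-support future temperatures
.pool_bin_for <- function(pool, bin) {
  ed <- pool$edges
  ed[pmax(1L, pmin(length(ed), findInterval(bin, ed)))]
}

#' Population-weighted national RMSE implied by the error models
#'
#' sqrt of the weighted mean over county-days of sigma_hat^2 + mu_hat^2:
#' the total second moment about zero, so conditional bias counts against
#' accuracy.
#'
#' @param var_model,mean_model fitted models.
#' @param climate_panel county-day panel with `temp`, `wfo_id`, `date`.
#' @param delta_override scenario-adjusted post-sample trend.
#' @param weights per-row weights (county population); default equal.
#' @return RMSE in deg C.
#' @export
implied_national_rmse <- function(var_model, mean_model, climate_panel,
                                  delta_override = NULL, weights = NULL) {
  cp <- as.data.table(climate_panel)
  if (nrow(cp) == 0) stop("empty climate panel")
  w <- weights %||% rep(1, nrow(cp))
  mu <- predict_error_mean(mean_model, cp$temp, cp$wfo_id)
  sdv <- predict_error_sd(var_model, cp$temp, cp$wfo_id, year(cp$date),
                          delta_override)
  sqrt(weighted.mean(sdv^2 + mu^2, w))
}

#' Calibrate the scenario variance trend to a 2100 RMSE target
#'
#' Finds the post-sample per-year log-variance trend delta such that the
#' population-weighted national RMSE implied by the error models over the
#' end-century climate panel equals the scenario target.  The implied RMSE
#' is strictly increasing in delta, so the root is unique; it is found by
#' bracketed root finding to |implied - target| < 1e-6 deg C.  The
#' `constant` scenario freezes the SD at its end-of-sample level
#' (delta = 0 after the sample); `zero_error` generates no errors at all.
#'
#' @param var_model,mean_model fitted models.
#' @param scenario name in `c("slowed", "central", "accelerated",
#'   "constant", "zero_error")`.
#' @param target_rmse_2100 target (deg C); ignored for `constant` and
#'   `zero_error`.
#' @param future_climate end-century county-day panel used for
#'   calibration.
#' @param weights calibration weights (county population).
#' @return list of class `scenario_trend`: `scenario`, `delta_adjusted`,
#'   `target_rmse_2100`, `achieved_rmse`.
#' @export
calibrate_scenario_trend <- function(var_model, mean_model, scenario,
                                     target_rmse_2100 = NULL,
                                     future_climate = NULL, weights = NULL) {
  scenario <- match.arg(scenario, c("slowed", "central", "accelerated",
                                    "constant", "zero_error"))
  out <- list(scenario = scenario, target_rmse_2100 = target_rmse_2100,
              delta_adjusted = NA_real_, achieved_rmse = NA_real_)
  class(out) <- "scenario_trend"
  if (scenario == "zero_error") {
    out$delta_adjusted <- -Inf
    return(out)
  }
  if (scenario == "constant") {
    out$delta_adjusted <- 0
    if (!is.null(future_climate))
      out$achieved_rmse <- implied_national_rmse(
        var_model, mean_model, future_climate, 0, weights)
    return(out)
  }
  stopifnot(!is.null(target_rmse_2100), !is.null(future_climate))
  if (target_rmse_2100 <= 0)
    stop("target must be > 0 (use the zero_error scenario for zero RMSE)")
  f <- function(d) implied_national_rmse(var_model, mean_model,
                                         future_climate, d, weights) -
    target_rmse_2100
  lo <- -0.5; hi <- 0.5
  while (f(lo) > 0 && lo > -100) lo <- lo * 2
  while (f(hi) < 0 && hi < 100) hi <- hi * 2
  if (f(lo) > 0 || f(hi) < 0)
    stop("target RMSE ", target_rmse_2100,
         " unreachable with finite trend in [", lo, ", ", hi, "]")
  root <- uniroot(f, c(lo, hi), tol = 1e-12)$root
  out$delta_adjusted <- root
  out$achieved_rmse <- target_rmse_2100 + f(root)
  out
}

#' Sample scenario-consistent future forecast errors
#'
#' For each future county-day, draws a standardized error uniformly with
#' replacement from the historical pool of the day's 5 degree C
#' temperature bin (nearest nonempty bin if the future temperature falls
#' outside the historical support) and reconstructs
#' e = mu_hat + sigma_hat(scenario, year) * e_tilde.  The `zero_error`
#' scenario returns all-zero errors.
#'
#' @param future_climate county-day panel with `temp`, `wfo_id`, `date`.
#' @param mean_model,var_model fitted models.
#' @param scenario a [calibrate_scenario_trend()] object.
#' @param pool a [standardize_errors()] pool.
#' @param seed integer seed.
#' @return the panel with columns `error` and `e_std` added.
#' @export
sample_future_errors <- function(future_climate, mean_model, var_model,
                                 scenario, pool, seed = 1L) {
  cp <- as.data.table(copy(future_climate))
  if (scenario$scenario == "zero_error") {
    cp[, `:=`(e_std = 0, error = 0)]
    return(cp[])
  }
  if (length(pool$bins) == 0) stop("empty standardized-error pool")
  bin <- .pool_bin_for(pool, 5 * floor(cp$temp / 5))
  with_seed(seed, {
    cp[, e_std := {
      b <- as.character(bin)
      z <- numeric(.N)
      for (bb in unique(b)) {
        idx <- which(b == bb)
        src <- pool$bins[[bb]]
        z[idx] <- src[sample.int(length(src), length(idx), replace = TRUE)]
      }
      z
    }]
  })
  mu <- predict_error_mean(mean_model, cp$temp, cp$wfo_id)
  sdv <- predict_error_sd(var_model, cp$temp, cp$wfo_id, year(cp$date),
                          scenario$delta_adjusted)
  cp[, error := mu + sdv * e_std]
  cp[]
}
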