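# Fully synthetic county panels with the statistical structure the analysis
# assumes: seasonal + AR(1) daily temperature, forecast errors whose
# conditional moments vary with temperature and improve over time, and
# county-month mortality generated from a known temperature-by-error
# response surface plus nuisance fixed effects.

#' Generate synthetic county profiles
#'
#' Counties are partitioned across states and weather forecast offices
#' (WFOs, the clustering unit for inference); every state and WFO receives
#' at least one county.  Climatological means, seasonal amplitudes,
#' day-to-day variability, initial forecast-error SDs, populations, and air
#' conditioning take-up are heterogeneous across counties.
#'
#' @param n_counties,n_states,n_wfos positive counts with
#'   `n_counties >= max(n_states, n_wfos)`.
#' @param seed integer seed.
#' @param mean_temp_range,seasonal_amp_range,day_sd_range,error_sd0_range
#'   ranges (deg C) for the county climatology draws.
#' @return a `data.table` with one row per county: `county_id`, `state_id`,
#'   `wfo_id`, `population_base`, `mean_temp`, `seasonal_amp`,
#'   `day_to_day_sd`, `error_sd0`, `ac_takeup`.
#' @export
generate_counties <- function(n_counties, n_states, n_wfos, seed = 1L,
                              mean_temp_range = c(2, 26),
                              seasonal_amp_range = c(6, 14),
                              day_sd_range = c(2, 4),
                              error_sd0_range = c(1.1, 2.2)) {
  if (n_counties < 1 || n_states < 1 || n_wfos < 1)
    stop("counts must be positive")
  if (n_counties < n_states || n_counties < n_wfos)
    stop("need at least one county per state and per WFO")
  with_seed(seed, {
    # guarantee every state/WFO is hit, then fill the rest at random
    state <- c(seq_len(n_states),
               sample.int(n_states, n_counties - n_states, replace = TRUE))
    wfo <- c(seq_len(n_wfos),
             sample.int(n_wfos, n_counties - n_wfos, replace = TRUE))
    dt <- data.table(
      county_id = sprintf("c%04d", seq_len(n_counties)),
      state_id = sprintf("s%03d", sample(state)),
      wfo_id = sprintf("w%03d", sample(wfo)),
      population_base = round(exp(rnorm(n_counties, 10.3, 0.9))),
      mean_temp = runif(n_counties, mean_temp_range[1], mean_temp_range[2]),
      seasonal_amp = runif(n_counties, seasonal_amp_range[1],
                           seasonal_amp_range[2]),
      day_to_day_sd = runif(n_counties, day_sd_range[1], day_sd_range[2]),
      error_sd0 = runif(n_counties, error_sd0_range[1], error_sd0_range[2]),
      ac_takeup = runif(n_counties)
    )
    dt
  })
}

#' Simulate daily county weather
#'
#' Daily mean temperature = county climatological mean + seasonal sinusoid
#' (peak near mid-July) + stationary AR(1) noise with marginal SD
#' `day_to_day_sd`.  Precipitation is a wet-day Bernoulli times a Gamma
#' amount (mm), nonnegative.
#'
#' @param counties output of [generate_counties()].
#' @param years integer vector of consecutive calendar years.
#' @param seed integer seed.
#' @param ar1 AR(1) coefficient of the temperature noise.
#' @return a county-day `data.table` with `county_id`, `date` (`IDate`),
#'   `temp`, `precip`.
#' @export
simulate_daily_weather <- function(counties, years, seed = 1L, ar1 = 0.7) {
  stopifnot(length(years) >= 1)
  dates <- seq(as.IDate(sprintf("%d-01-01", min(years))),
               as.IDate(sprintf("%d-12-31", max(years))), by = 1L)
  nd <- length(dates)
  doy <- yday(dates)
  seas_shape <- cos(2 * pi * (doy - 199) / 365.25)
  with_seed(seed, {
    out <- vector("list", nrow(counties))
    for (i in seq_len(nrow(counties))) {
      ci <- counties[i]
      innov_sd <- ci$day_to_day_sd * sqrt(1 - ar1^2)
      z <- as.numeric(
        stats::filter(rnorm(nd, 0, innov_sd), ar1, "recursive",
                      init = rnorm(1, 0, ci$day_to_day_sd)))
      wet <- rbinom(nd, 1L, 0.3)
      out[[i]] <- data.table(
        county_id = ci$county_id,
        date = dates,
        temp = ci$mean_temp + ci$seasonal_amp * seas_shape + z,
        precip = wet * rgamma(nd, shape = 0.7, scale = 8))
    }
    rbindlist(out)
  })
}

#' Default conditional forecast-error process
#'
#' Encodes the documented structure of day-ahead temperature forecast
#' errors (error = forecast - realization): forecasts run warm on cold days
#' and cool on hot days (decreasing conditional mean through ~20 deg C);
#' the conditional SD shrinks with temperature; errors are right-skewed
#' when cold and left-skewed when hot; hot days carry excess kurtosis via a
#' two-point scale mixture; and the SD declines by a fixed percentage per
#' year (default -2.3%/yr, consistent with roughly a one-third RMSE
#' improvement over two decades).
#'
#' @param sd_annual_trend proportional per-year change in the error SD.
#' @return a list of curves and mixture settings for
#'   [simulate_forecast_errors()].
#' @export
default_error_process <- function(sd_annual_trend = -0.023) {
  list(
    mean_curve = function(temp) 0.015 * (20 - temp),
    sd_curve = function(temp) pmax(1.25 - 0.012 * temp, 0.6),
    sd_annual_trend = sd_annual_trend,
    skew_curve = function(temp) -0.15 * (temp - 20),
    tail_mix = list(threshold = 25, prob = 0.05, scale_hi = 2.5)
  )
}

#' Simulate day-ahead forecast errors
#'
#' Fills `forecast` and `error` on a daily weather panel.  Conditional on
#' temperature and year, errors have mean `mean_curve(temp)` and SD
#' `error_sd0_c * sd_curve(temp) * (1 + sd_annual_trend)^(year - year0)`;
#' the standardized shock is a skew-normal with shape `skew_curve(temp)`,
#' and on days hotter than the tail-mix threshold it is multiplied by a
#' variance-preserving two-point scale mixture that injects excess
#' kurtosis.
#'
#' @param records daily weather panel from [simulate_daily_weather()].
#' @param counties county profiles (for `error_sd0`).
#' @param error_process list as returned by [default_error_process()];
#'   set `skew_curve` to `function(t) 0 * t` and `tail_mix$prob = 0` for a
#'   Gaussian process.
#' @param seed integer seed.
#' @return the records with `forecast` and `error` columns
#'   (`error = forecast - temp` exactly).
#' @export
simulate_forecast_errors <- function(records, counties,
                                     error_process = default_error_process(),
                                     seed = 1L) {
  ep <- error_process
  if (abs(ep$sd_annual_trend) >= 1)
    stop("|sd_annual_trend| must be < 1")
  rec <- copy(records)
  rec[counties, error_sd0 := i.error_sd0, on = "county_id"]
  year0 <- min(year(rec$date))
  with_seed(seed, {
    n <- nrow(rec)
    alpha <- ep$skew_curve(rec$temp)
    delta <- alpha / sqrt(1 + alpha^2)
    # standardized skew-normal draw: delta|u0| + sqrt(1-delta^2) u1, centered
    u0 <- abs(rnorm(n)); u1 <- rnorm(n)
    m <- sqrt(2 / pi) * delta
    s <- sqrt(1 - m^2)
    z <- (delta * u0 + sqrt(1 - delta^2) * u1 - m) / s
    tm <- ep$tail_mix
    if (!is.null(tm) && tm$prob > 0) {
      hot <- rec$temp > tm$threshold
      s_lo <- sqrt((1 - tm$prob * tm$scale_hi^2) / (1 - tm$prob))
      if (!is.finite(s_lo) || s_lo <= 0)
        stop("tail_mix prob * scale_hi^2 must be < 1")
      mix <- ifelse(runif(n) < tm$prob, tm$scale_hi, s_lo)
      z <- ifelse(hot, z * mix, z)
    }
    sdv <- rec$error_sd0 * ep$sd_curve(rec$temp) *
      (1 + ep$sd_annual_trend)^(year(rec$date) - year0)
    if (any(sdv < 0)) stop("sd_curve must be nonnegative")
    rec[, error := ep$mean_curve(temp) + sdv * z]
    rec[, forecast := temp + error]
    rec[, error_sd0 := NULL]
  })
  rec[]
}

#' Construct a known truth response surface
#'
#' Builds a 13-coefficient truth vector on the daily basis whose pure
#' temperature curve (at zero error) is U-shaped with an interior minimum,
#' and whose forecast-error response is convex with a critical point at
#' e = 0 at every temperature (the slope of the error spline at zero is
#' cancelled within each interaction block).  Error effects grow with
#' temperature, so misforecasts are deadliest on hot days.
#'
#' @param knots numeric 4-vector of error-spline knots used for generation.
#' @param temp_vertex temperature (deg C) of the planted quartic vertex.
#' @param temp_scale,error_scale magnitudes of the temperature and error
#'   responses (deaths per 100,000 per day at reference displacements).
#' @param fe_scale_county_month,fe_scale_state_time,trend_scale,noise_sd
#'   SDs of the nuisance components on the monthly mortality-rate scale.
#' @param rain_coef coefficient on the above-median-rainfall indicator.
#' @param baseline baseline monthly mortality rate (deaths per 100,000).
#' @return a list of class `truth_surface` with `beta_true` (13), the
#'   nuisance scales, `mmt_true`, `knots`, `baseline`, `rain_coef`.
#' @export
make_truth_surface <- function(knots = c(-1.7, -0.4, 0.3, 1.8),
                               temp_vertex = 25,
                               temp_scale = 4e-4,
                               error_scale = 1.5e-2,
                               fe_scale_county_month = 8,
                               fe_scale_state_time = 3,
                               trend_scale = 0.02,
                               noise_sd = 4,
                               rain_coef = 0.5,
                               baseline = 75) {
  # pure temperature quartic with vertex at temp_vertex (constant absorbed
  # by fixed effects, so only powers 1..4 matter for identification)
  a2 <- temp_scale; a4 <- temp_scale / 900
  beta_T <- c(-2 * a2 * temp_vertex - 4 * a4 * temp_vertex^3,
              a2 + 6 * a4 * temp_vertex^2,
              -4 * a4 * temp_vertex,
              a4)
  # error response: for each interaction block g in {1, T, T^2}, choose the
  # curvature columns (N2, N3) and cancel the slope at e = 0 via N1
  Np0 <- spline_slope_at_zero(knots)           # (N1', N2', N3')(0)
  blk <- function(c2, c3) c(-(c2 * Np0[2] + c3 * Np0[3]) / Np0[1], c2, c3)
  beta_e  <- error_scale * blk(0.8, 0.6)       # level block
  beta_eT <- error_scale * 0.01 * blk(0.5, 0.4)   # x T
  beta_eT2 <- error_scale * 0.002 * blk(1.0, 0.8) # x T^2
  beta <- c(beta_T, beta_e, beta_eT, beta_eT2)
  names(beta) <- paste0("x", 1:13)
  tt <- list(beta_true = beta, knots = knots,
             fe_scale_county_month = fe_scale_county_month,
             fe_scale_state_time = fe_scale_state_time,
             trend_scale = trend_scale, noise_sd = noise_sd,
             rain_coef = rain_coef, baseline = baseline)
  tg <- seq(10, 35, by = 0.01)
  curve0 <- build_daily_basis(tg, rep(0, length(tg)),
                              basis_spec(knots = knots)) %*% beta
  tt$mmt_true <- tg[which.min(curve0)]
  class(tt) <- "truth_surface"
  tt
}

# derivative of the 3 natural-spline basis functions at e = 0
spline_slope_at_zero <- function(knots, h = 1e-6) {
  (spline_basis(h, knots) - spline_basis(-h, knots)) / (2 * h)
}

#' Simulate county-month mortality from a truth surface
#'
#' Inverts the estimating equation as a generative model: the monthly
#' mortality rate is the sum over days of the 13-column basis times
#' `beta_true`, plus a rainfall term, county-month fixed effects,
#' county-month linear trends in the month index, state-year-month shocks,
#' and i.i.d. noise.  All additive components are returned as columns so
#' oracle tests can reconstruct the rate exactly.
#'
#' @param records county-day records with `error_demeaned` (run
#'   [demean_errors()] first).
#' @param counties county profiles.
#' @param truth a [make_truth_surface()] object.
#' @param seed integer seed.
#' @return county-month `data.table` with `mortality_rate` and component
#'   columns `comp_signal`, `comp_rain`, `comp_fe_cm`, `comp_trend`,
#'   `comp_fe_st`, `comp_noise`.
#' @export
simulate_mortality <- function(records, counties, truth, seed = 1L) {
  if (!"error_demeaned" %in% names(records))
    stop("records lack demeaned errors; call demean_errors() first")
  stopifnot(inherits(truth, "truth_surface"))
  X <- build_daily_basis(records$temp, records$error_demeaned,
                         basis_spec(knots = truth$knots))
  dt <- data.table(county_id = records$county_id,
                   year = year(records$date),
                   month = month(records$date),
                   signal_d = as.numeric(X %*% truth$beta_true),
                   precip = records$precip)
  mo <- dt[, .(comp_signal = sum(signal_d), precip = sum(precip)),
           by = .(county_id, year, month)]
  mo[, rain_above_median := as.numeric(precip > stats::median(precip)),
     by = county_id]
  mo[, precip := NULL]
  mo[counties, state_id := i.state_id, on = "county_id"]
  ym0 <- min(mo$year * 12L + mo$month)
  mo[, month_index := year * 12L + month - ym0]
  with_seed(seed, {
    cm <- unique(mo[, .(county_id, month)])
    cm[, fe_cm := rnorm(.N, 0, truth$fe_scale_county_month)]
    cm[, trend_cm := rnorm(.N, 0, truth$trend_scale)]
    st <- unique(mo[, .(state_id, year, month)])
    st[, fe_st := rnorm(.N, 0, truth$fe_scale_state_time)]
    mo[cm, `:=`(fe_cm = i.fe_cm, trend_cm = i.trend_cm),
       on = c("county_id", "month")]
    mo[st, fe_st := i.fe_st, on = c("state_id", "year", "month")]
    mo[, comp_rain := truth$rain_coef * rain_above_median]
    mo[, comp_fe_cm := truth$baseline + fe_cm]
    mo[, comp_trend := trend_cm * month_index]
    mo[, comp_fe_st := fe_st]
    mo[, comp_noise := rnorm(.N, 0, truth$noise_sd)]
  })
  mo[, mortality_rate := comp_signal + comp_rain + comp_fe_cm +
       comp_trend + comp_fe_st + comp_noise]
  mo[, c("fe_cm", "trend_cm", "fe_st") := NULL]
  setkey(mo, county_id, year, month)
  mo[]
}

#' Impute suppressed county-month mortality from state rates
#'
#' Replaces flagged county-month rates by the population-weighted
#' state-month mean rate computed from the unsuppressed counties of the
#' same state-month.  A state-month whose counties are all suppressed has
#' no donor and is an error.
#'
#' @param monthly county-month table with `mortality_rate`, `county_id`,
#'   `year`, `month`.
#' @param suppressed logical vector (or column name) flagging suppressed
#'   county-months.
#' @param counties county profiles (for `state_id` and weights).
#' @return the table with suppressed cells imputed and a logical `imputed`
#'   column.
#' @export
impute_missing_mortality <- function(monthly, suppressed, counties) {
  mo <- copy(monthly)
  stopifnot(length(suppressed) == nrow(mo))
  mo[, imputed := as.logical(suppressed)]
  if (!"state_id" %in% names(mo))
    mo[counties, state_id := i.state_id, on = "county_id"]
  mo[counties, pop := i.population_base, on = "county_id"]
  donors <- mo[imputed == FALSE,
               .(state_rate = weighted.mean(mortality_rate, pop)),
               by = .(state_id, year, month)]
  need <- unique(mo[imputed == TRUE, .(state_id, year, month)])
  orphan <- need[!donors, on = c("state_id", "year", "month")]
  if (nrow(orphan) > 0)
    stop("state-months with all counties suppressed (no donor): ",
         paste(orphan$state_id, orphan$year, orphan$month, collapse = "; "))
  mo[donors, state_rate := i.state_rate, on = c("state_id", "year", "month")]
  mo[imputed == TRUE, mortality_rate := state_rate]
  mo[, c("state_rate", "pop") := NULL]
  mo[]
}

#' Default truth laws for synthetic expert elicitation
#'
#' Per-horizon skew-lognormal laws for the multiplicative change in
#' forecast RMSE, centred near one-half by 2100 (the median expert expects
#' RMSE to roughly halve) with right skew (a pessimistic tail including
#' degradation, change > 1).
#' @return list with `h2050` and `h2100` parameter lists `(xi, omega, alpha)`.
#' @export
default_expert_laws <- function() {
  list(h2050 = list(xi = log(0.75), omega = 0.25, alpha = 1.5),
       h2100 = list(xi = log(0.50), omega = 0.40, alpha = 2.0))
}

#' Simulate expert survey responses
#'
#' Each synthetic expert reports 2005 and 2020 accuracy plus
#' (best-case, median, worst-case) = (1st, 50th, 99th percentile) accuracy
#' for 2050 and 2100.  Percentile triplets are the exact quantiles of a
#' known skew-lognormal change law (expert-specific jitter on the location)
#' applied to the expert's 2020 accuracy.  A configurable share of experts
#' reports MAE with a known linear RMSE = `mae_a + mae_b * MAE` relation,
#' and one (optionally) reports MSE.
#'
#' @param n_experts number of experts (>= 1).
#' @param truth_laws per-horizon laws, see [default_expert_laws()].
#' @param seed integer seed.
#' @param frac_mae fraction of experts reporting in MAE units.
#' @param mae_a,mae_b the linear MAE-to-RMSE relation used for generation.
#' @return a `data.table`, one row per expert-horizon, with columns
#'   `expert`, `metric`, `acc_2005`, `acc_2020`, `horizon`, `p01`, `p50`,
#'   `p99`, and the generating `xi`, `omega`, `alpha`.
#' @export
simulate_expert_responses <- function(n_experts, truth_laws = default_expert_laws(),
                                      seed = 1L, frac_mae = 0.3,
                                      mae_a = 0, mae_b = 1.25) {
  stopifnot(n_experts >= 1)
  with_seed(seed, {
    rmse_2020 <- exp(rnorm(n_experts, log(1.3), 0.15))
    rmse_2005 <- rmse_2020 / exp(rnorm(n_experts, log(0.66), 0.05))
    is_mae <- runif(n_experts) < frac_mae
    out <- list()
    for (i in seq_len(n_experts)) {
      for (hz in c(2050, 2100)) {
        law <- truth_laws[[paste0("h", hz)]]
        xi_i <- law$xi + rnorm(1, 0, 0.05)
        q <- exp(xi_i + law$omega *
                   qsn_standard(c(0.01, 0.5, 0.99), law$alpha))
        acc <- rmse_2020[i] * q         # accuracy: smaller = better
        metric <- if (is_mae[i]) "MAE" else "RMSE"
        conv <- function(x) if (is_mae[i]) (x - mae_a) / mae_b else x
        out[[length(out) + 1L]] <- data.table(
          expert = i, metric = metric, horizon = hz,
          acc_2005 = conv(rmse_2005[i]), acc_2020 = conv(rmse_2020[i]),
          p01 = conv(acc[1]), p50 = conv(acc[2]), p99 = conv(acc[3]),
          xi = xi_i, omega = law$omega, alpha = law$alpha)
      }
    }
    rbindlist(out)
  })
}

#' Build a future climate scenario panel
#'
#' The no-change scenario copies reference-period daily temperatures to the
#' evaluation years unchanged.  Warming scenarios add a linear ramp that
#' reaches `warming_delta` deg C at the final evaluation year.
#'
#' @param records historical county-day records containing the reference
#'   years.
#' @param spec list with `name`, `warming_delta` (deg C), `eval_years`,
#'   `reference_years` (equal-length year vectors, conventionally six
#'   consecutive years each).
#' @return future county-day `data.table` with `county_id`, `date`, `temp`,
#'   `scenario`.
#' @export
make_climate_scenario <- function(records, spec) {
  stopifnot(length(spec$eval_years) == length(spec$reference_years))
  yrs <- year(records$date)
  if (!all(spec$reference_years %in% yrs))
    stop("reference years missing from records: ",
         paste(setdiff(spec$reference_years, yrs), collapse = ", "))
  y_end <- max(spec$eval_years)
  y0 <- max(spec$reference_years)
  out <- vector("list", length(spec$eval_years))
  for (k in seq_along(spec$eval_years)) {
    ye <- spec$eval_years[k]; yr <- spec$reference_years[k]
    base <- records[year(date) == yr,
                    .(county_id, date, temp)]
    # map the reference date to the same month/day in the eval year
    base[, date := as.IDate(sprintf("%d-%02d-%02d", ye,
                                    month(date), mday(date)))]
    base <- base[!is.na(date)]
    ramp <- if (y_end == y0) 1 else (ye - y0) / (y_end - y0)
    base[, temp := temp + spec$warming_delta * ramp]
    out[[k]] <- base
  }
  res <- rbindlist(out)
  res[, scenario := spec$name]
  setkey(res, county_id, date)
  res[]
}
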