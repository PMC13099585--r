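test_that("county generation partitions states and WFOs correctly", {
  one <- generate_counties(1, 1, 1, seed = 7)
  expect_identical(nrow(one), 1L)
  expect_identical(one$state_id, "s001")
  expect_identical(one$wfo_id, "w001")

  a <- generate_counties(200, 20, 10, seed = 1)
  b <- generate_counties(200, 20, 10, seed = 1)
  expect_identical(a, b)

  counts <- a[, .N, by = wfo_id]
  expect_identical(uniqueN(a$wfo_id), 10L)
  expect_true(all(counts$N >= 1))
  expect_identical(sum(counts$N), 200L)
  expect_identical(uniqueN(a$state_id), 20L)
  # each county maps to exactly one state and WFO by construction
  expect_identical(uniqueN(a$county_id), 200L)
  expect_true(all(a$population_base > 0))
  expect_true(all(a$ac_takeup >= 0 & a$ac_takeup <= 1))

  expect_error(generate_counties(0, 1, 1))
  expect_error(generate_counties(5, 6, 1))
})

test_that("daily weather has the requested climatology", {
  cty <- data.table(county_id = "a", state_id = "s", wfo_id = "w",
                    population_base = 1, mean_temp = 12, seasonal_amp = 0,
                    day_to_day_sd = 0, error_sd0 = 1, ac_takeup = 0.5)
  wx <- simulate_daily_weather(cty, 2005, seed = 3)
  expect_equal(wx$temp, rep(12, nrow(wx)))
  expect_true(all(wx$precip >= 0))

  # CLT check: AR(1) with marginal SD s and coefficient phi has
  # var(mean) ~ s^2/n * (1+phi)/(1-phi)
  cty2 <- copy(cty)[, day_to_day_sd := 3]
  wx2 <- simulate_daily_weather(cty2, 1990:2017, seed = 4)  # ~10k days
  n <- nrow(wx2)
  se <- 3 / sqrt(n) * sqrt((1 + 0.7) / (1 - 0.7))
  expect_lt(abs(mean(wx2$temp) - 12), 3 * se)

  expect_identical(simulate_daily_weather(cty2, 2005:2006, seed = 9),
                   simulate_daily_weather(cty2, 2005:2006, seed = 9))
})

test_that("forecast errors match the requested conditional moments", {
  cty <- data.table(county_id = "a", state_id = "s", wfo_id = "w",
                    population_base = 1, mean_temp = 15, seasonal_amp = 12,
                    day_to_day_sd = 4, error_sd0 = 1, ac_takeup = 0.5)
  # plain process: mean 0, sd 1, no trend, no skew, no tails; 1e5 draws
  # with uniform temperature coverage so every 5-degree bin is well filled
  ep <- list(mean_curve = function(t) 0 * t,
             sd_curve = function(t) rep(1, length(t)),
             sd_annual_trend = 0,
             skew_curve = function(t) 0 * t,
             tail_mix = list(threshold = Inf, prob = 0, scale_hi = 1))
  set.seed(5)
  n_mc <- 4e5    # ~44k draws per 5-degree bin, so 0.02 is > 4 SEs
  wx <- data.table(county_id = "a",
                   date = as.IDate("2005-01-01") + sample(0:364, n_mc, TRUE),
                   temp = runif(n_mc, -10, 35), precip = 0)
  rec <- simulate_forecast_errors(wx, cty, ep, seed = 6)
  expect_equal(rec$error, rec$forecast - rec$temp)
  bs <- data.table(e = rec$error, bin = 5 * floor(rec$temp / 5))[
    , .(m = mean(e), s = sd(e), .N), by = bin]
  expect_lt(max(abs(bs$m)), 0.02)
  expect_true(all(bs$s > 0.98 & bs$s < 1.02))

  # declining SD trend: pooled SD ratio last/first year ~ (1+trend)^(nyr-1)
  ep2 <- ep; ep2$sd_annual_trend <- -0.03
  set.seed(7)
  wx2 <- data.table(county_id = "a",
                    date = as.IDate("2005-01-01") +
                      sample(0:(365 * 19 - 1), 2e5, TRUE),
                    temp = runif(2e5, -10, 35), precip = 0)
  rec2 <- simulate_forecast_errors(wx2, cty, ep2, seed = 8)
  yr <- year(rec2$date)
  ratio <- sd(rec2$error[yr == 2023]) / sd(rec2$error[yr == 2005])
  expect_equal(ratio, 0.97^18, tolerance = 0.03)

  # degenerate: sd 0 -> error equals the conditional mean exactly
  ep3 <- ep; ep3$sd_curve <- function(t) rep(0, length(t))
  ep3$mean_curve <- function(t) 0.1 * t
  rec3 <- simulate_forecast_errors(wx, cty, ep3, seed = 9)
  expect_equal(rec3$error, 0.1 * rec3$temp)

  ep4 <- ep; ep4$sd_annual_trend <- -1.5
  expect_error(simulate_forecast_errors(wx, cty, ep4, seed = 1))
})

test_that("skewness sign follows the skew curve and hot days gain kurtosis", {
  cty <- data.table(county_id = sprintf("k%02d", 1:20), state_id = "s",
                    wfo_id = "w", population_base = 1, mean_temp = 15,
                    seasonal_amp = 14, day_to_day_sd = 4, error_sd0 = 1,
                    ac_takeup = 0.5)
  wx <- simulate_daily_weather(cty, 2005:2016, seed = 10)
  rec <- simulate_forecast_errors(wx, cty, default_error_process(0),
                                  seed = 11)
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  kurt <- function(x) mean((x - mean(x))^4) / sd(x)^4 - 3
  cold <- rec[temp < 5]$error; hot <- rec[temp > 27]$error
  expect_gt(skew(cold), 0.05)   # forecasts skew warm on cold days
  expect_lt(skew(hot), -0.05)   # and cool on hot days
  mild <- rec[temp > 10 & temp < 20]$error
  expect_gt(kurt(hot), kurt(mild) + 0.3)  # fat tails when hot
})

test_that("mortality generator components add up and degenerate limits hold", {
  # null response: constant T at the MMT and e = 0 -> rate = baseline
  truth <- noiseless_truth()
  cty <- data.table(county_id = "a", state_id = "s", wfo_id = "w",
                    population_base = 100, mean_temp = truth$mmt_true,
                    seasonal_amp = 0, day_to_day_sd = 0, error_sd0 = 0,
                    ac_takeup = 0.5)
  wx <- simulate_daily_weather(cty, 2005, seed = 1)
  rec <- copy(wx)[, `:=`(forecast = temp, error = 0, error_demeaned = 0,
                         precip = 0)]
  mo <- simulate_mortality(rec, cty, truth, seed = 2)
  base_contrib <- as.numeric(
    build_daily_basis(truth$mmt_true, 0, basis_spec(knots = truth$knots))
    %*% truth$beta_true)
  days <- mo[, .N]  # one county, 12 months
  expect_identical(days, 12L)
  ndays <- data.table(m = month(wx$date))[, .N, by = m]$N
  expect_equal(mo$mortality_rate, truth$baseline + ndays * base_contrib)

  # beta = 0 -> rate equals the sum of nuisance components only
  fx <- fixture_panel()
  truth0 <- make_truth_surface(temp_scale = 0, error_scale = 0)
  truth0$beta_true[] <- 0
  mo2 <- simulate_mortality(fx$records, fx$counties, truth0, seed = 3)
  expect_equal(mo2$mortality_rate,
               mo2$comp_rain + mo2$comp_fe_cm + mo2$comp_trend +
                 mo2$comp_fe_st + mo2$comp_noise)
  expect_true(all(mo2$comp_signal == 0))

  # components always reconstruct the emitted rate
  mo3 <- fx$mortality
  expect_equal(mo3$mortality_rate,
               mo3$comp_signal + mo3$comp_rain + mo3$comp_fe_cm +
                 mo3$comp_trend + mo3$comp_fe_st + mo3$comp_noise)

  expect_error(simulate_mortality(copy(fx$records)[, error_demeaned := NULL],
                                  fx$counties, truth, seed = 1))
})

test_that("state-rate imputation matches brute-force recomputation", {
  fx <- fixture_panel()
  mo <- fx$mortality
  # empty mask: unchanged
  un <- impute_missing_mortality(mo, rep(FALSE, nrow(mo)), fx$counties)
  expect_equal(un$mortality_rate, mo$mortality_rate)

  # two-county state, one suppressed: imputed to the donor's rate
  cty <- data.table(county_id = c("a", "b"), state_id = "s1",
                    wfo_id = "w", population_base = c(10, 20))
  mo2 <- data.table(county_id = c("a", "b"), year = 2005L, month = 1L,
                    mortality_rate = c(1.0, 3.0))
  imp <- impute_missing_mortality(mo2, c(TRUE, FALSE), cty)
  expect_equal(imp[county_id == "a"]$mortality_rate, 3.0)

  # random 5% mask equals an independently recomputed state-month mean
  set.seed(42)
  mask <- runif(nrow(mo)) < 0.05
  imp2 <- impute_missing_mortality(mo, mask, fx$counties)
  pop <- fx$counties$population_base[match(mo$county_id,
                                           fx$counties$county_id)]
  st <- fx$counties$state_id[match(mo$county_id, fx$counties$county_id)]
  key <- paste(st, mo$year, mo$month)
  for (i in which(mask)) {
    don <- which(key == key[i] & !mask)
    expected <- sum(mo$mortality_rate[don] * pop[don]) / sum(pop[don])
    expect_equal(imp2$mortality_rate[i], expected)
  }
  # all-suppressed state-month has no donor
  expect_error(impute_missing_mortality(mo2, c(TRUE, TRUE), cty),
               "no donor")
})

test_that("expert responses encode their generating laws", {
  # symmetric law: log-spacings of the percentiles are equal
  laws <- list(h2050 = list(xi = log(0.8), omega = 0.2, alpha = 0),
               h2100 = list(xi = log(0.5), omega = 0.3, alpha = 0))
  r <- simulate_expert_responses(6, laws, seed = 20, frac_mae = 0)
  expect_true(all(r$metric == "RMSE"))
  expect_equal(log(r$p99 / r$p50), log(r$p50 / r$p01), tolerance = 1e-8)
  expect_true(all(r$p01 <= r$p50 & r$p50 <= r$p99))
  expect_true(all(r$p01 > 0))

  # known law round trip through the percentile calibration
  r1 <- simulate_expert_responses(1, seed = 21, frac_mae = 0)
  row <- r1[horizon == 2100]
  f <- fit_skew_lognormal(row$p01 / row$acc_2020, row$p50 / row$acc_2020,
                          row$p99 / row$acc_2020)
  gen_q <- exp(row$xi + row$omega * qsn_standard(c(0.25, 0.75), row$alpha))
  expect_rel_equal(qslnorm(c(0.25, 0.75), f), gen_q, 1e-4)

  # single expert: mixture equals that expert's law
  m <- build_mixture(list(f))
  expect_equal(qmix(m, 0.5), qslnorm(0.5, f), tolerance = 1e-8)
})

test_that("climate scenarios copy, warm, and order correctly", {
  fx <- fixture_panel()
  base <- fx$records[, .(county_id, date, temp)]
  sp0 <- list(name = "none", warming_delta = 0,
              eval_years = 2095:2098, reference_years = 2005:2008)
  s0 <- make_climate_scenario(base, sp0)
  ref <- base[year(date) %in% 2005:2008]
  expect_equal(mean(s0$temp), mean(ref[!(month(date) == 2 & mday(date) == 29)]$temp),
               tolerance = 1e-10)
  expect_equal(sort(unique(year(s0$date))), 2095:2098)

  sp1 <- list(name = "warm", warming_delta = 3.8,
              eval_years = 2095:2098, reference_years = 2005:2008)
  s1 <- make_climate_scenario(base, sp1)
  shift <- mean(s1$temp) - mean(s0$temp)
  # ramp reaches 3.8 at the final eval year; earlier years are below it
  expect_gt(shift, 3.8 * 0.9)
  expect_lte(shift, 3.8 + 1e-9)

  sp2 <- list(name = "warm2", warming_delta = 1.6,
              eval_years = 2095:2098, reference_years = 2005:2008)
  s2 <- make_climate_scenario(base, sp2)
  expect_true(all(s2$temp <= s1$temp))   # pointwise ordering of deltas
  expect_true(all(s2$temp >= s0$temp))

  expect_error(make_climate_scenario(base, list(name = "x", warming_delta = 0,
    eval_years = 2095:2098, reference_years = 1990:1993)))
})
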