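# End-to-end orchestration of the analysis chain at a configurable scale.
# The numbered scripts under analysis/ are thin drivers over these
# functions; tests and the acceptance script call them directly.

#' Default pipeline configuration
#'
#' Desk-scale defaults: the panel dimensions and process parameters the
#' synthetic study is run at.  Scenario periods mirror the convention of
#' six-year reference (2015-2020) and evaluation (2095-2100) windows.
#'
#' @param n_counties,n_states,n_wfos panel dimensions.
#' @param years sample years of the historical panel.
#' @param n_experts number of synthetic experts in the elicitation.
#' @param warming_deltas named end-century warming (deg C) per climate
#'   scenario.
#' @param n_ci_draws coefficient draws for projection CIs.
#' @return a named list.
#' @export
pipeline_config <- function(n_counties = 40, n_states = 8, n_wfos = 8,
                            years = 2005:2012, n_experts = 11,
                            warming_deltas = c(no_change = 0, moderate = 2.7,
                                               high = 3.8),
                            n_ci_draws = 200L) {
  list(n_counties = n_counties, n_states = n_states, n_wfos = n_wfos,
       years = years, n_experts = n_experts,
       warming_deltas = warming_deltas, n_ci_draws = n_ci_draws,
       reference_years = 2015:2020, eval_years = 2095:2100)
}

#' Run the full analysis chain on synthetic data
#'
#' Stages: (1) simulate the county panel (weather, forecast errors,
#' mortality) from a known truth surface; (2) build the 13-column design
#' and fit the fixed-effects panel model; (3) fit the conditional
#' forecast-error models and standardized pool; (4) simulate and aggregate
#' the expert elicitation into scenario RMSE targets; (5) calibrate
#' scenario variance trends, draw future errors, and project lives saved
#' under each climate x forecast scenario pair.
#'
#' @param config a [pipeline_config()].
#' @param seed master seed; per-stage seeds are derived from it.
#' @return a list with the artifacts of every stage.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L) {
  seed <- as.integer(seed)
  seeds <- seed + c(sim = 0L, err = 1L, mort = 2L, expert = 3L,
                    draw = 4L, ci = 5L)
  truth <- make_truth_surface()

  # -- stage 1: synthetic panel
  counties <- generate_counties(config$n_counties, config$n_states,
                                config$n_wfos, seed = seeds["sim"])
  wx <- simulate_daily_weather(counties, config$years, seed = seeds["sim"])
  rec <- simulate_forecast_errors(wx, counties, seed = seeds["err"])
  rec <- demean_errors(rec, "county")
  rec[counties, `:=`(wfo_id = i.wfo_id, state_id = i.state_id),
      on = "county_id"]
  mort <- simulate_mortality(rec, counties, truth, seed = seeds["mort"])

  # -- stage 2: design + panel fit
  popw <- counties$population_base[match(rec$county_id, counties$county_id)]
  spec <- resolve_knots(rec, basis_spec(), weights = popw)
  design <- aggregate_monthly(rec, mort, counties, spec)
  fit <- fit_panel(design)

  # -- stage 3: conditional error models
  mean_model <- fit_error_mean(rec, weights = popw)
  var_model <- fit_error_variance(rec, mean_model, weights = popw)
  pool <- standardize_errors(rec, mean_model, var_model)

  # -- stage 4: elicitation
  experts <- simulate_expert_responses(config$n_experts,
                                       seed = seeds["expert"])
  hist_pairs <- data.frame(mae = seq(0.8, 2.0, length.out = 20))
  hist_pairs$rmse <- 1.25 * hist_pairs$mae
  experts_rmse <- convert_mae_to_rmse(experts, hist_pairs)
  changes <- normalize_changes(experts_rmse)
  fits_2100 <- lapply(which(changes$horizon == 2100), function(i)
    fit_skew_lognormal(changes$chg01[i], changes$chg50[i], changes$chg99[i]))
  mixture <- build_mixture(fits_2100)
  base_rmse_2020 <- implied_national_rmse(
    var_model, mean_model,
    rec[year(date) == max(config$years)], weights = NULL)
  targets <- scenario_targets(mixture, base_rmse_2020)

  # -- stage 5: projection
  # extend weather through the reference period so climate scenarios can
  # copy from it; reuse the historical process (trend applied via models)
  ref_wx <- simulate_daily_weather(counties, config$reference_years,
                                   seed = seeds["sim"] + 100L)
  ref_rec <- rbind(wx[, .(county_id, date, temp)],
                   ref_wx[, .(county_id, date, temp)])
  response <- make_response_function(fit)
  populations <- setNames(counties$population_base, counties$county_id)
  wfo_map <- setNames(counties$wfo_id, counties$county_id)
  results <- list()
  for (cs in names(config$warming_deltas)) {
    clim <- make_climate_scenario(ref_rec, list(
      name = cs, warming_delta = config$warming_deltas[[cs]],
      eval_years = config$eval_years,
      reference_years = config$reference_years))
    clim[, wfo_id := wfo_map[county_id]]
    clim_pop <- populations[clim$county_id]
    trends <- list(
      constant = calibrate_scenario_trend(var_model, mean_model, "constant",
                                          future_climate = clim,
                                          weights = clim_pop),
      slowed = calibrate_scenario_trend(var_model, mean_model, "slowed",
        targets[name == "slowed"]$rmse_2100, clim, clim_pop),
      central = calibrate_scenario_trend(var_model, mean_model, "central",
        targets[name == "central"]$rmse_2100, clim, clim_pop),
      accelerated = calibrate_scenario_trend(var_model, mean_model,
        "accelerated", targets[name == "accelerated"]$rmse_2100, clim,
        clim_pop),
      zero_error = calibrate_scenario_trend(var_model, mean_model,
                                            "zero_error"))
    projs <- lapply(trends, function(tr) {
      drawn <- sample_future_errors(clim, mean_model, var_model, tr, pool,
                                    seed = seeds["draw"])
      annual_excess_mortality(drawn, response, populations)
    })
    saved <- rbindlist(lapply(setdiff(names(projs), "constant"), function(s) {
      ls <- lives_saved(projs[[s]], projs$constant, fit,
                        n_draws = config$n_ci_draws, seed = seeds["ci"])
      ls[, `:=`(climate_scenario = cs, forecast_scenario = s)]
      ls
    }))
    results[[cs]] <- list(projections = projs, lives_saved = saved)
  }
  lives_table <- rbindlist(lapply(results, `[[`, "lives_saved"))
  list(truth = truth, counties = counties, records = rec,
       mortality = mort, design = design, fit = fit,
       mean_model = mean_model, var_model = var_model, pool = pool,
       experts = experts, mixture = mixture, targets = targets,
       base_rmse_2020 = base_rmse_2020, response = response,
       results = results, lives_saved = lives_table, config = config,
       seed = seed)
}
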