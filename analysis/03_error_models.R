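#!/usr/bin/env Rscript
# Stage 3 — conditional forecast-error models.
#
# Fits the spline conditional-mean model and the Gamma GLM (log link)
# conditional-variance model with an annual trend, standardizes the
# historical errors, and pools them in 5 C temperature bins for
# resampling.  The fitted annual trend is the quantity the accuracy
# scenarios later adjust.

source("analysis/00_config.R")

cfg <- ANALYSIS_CFG
counties <- generate_counties(cfg$n_counties, cfg$n_states, cfg$n_wfos,
                              seed = stage_seed(0))
wx <- simulate_daily_weather(counties, cfg$years, seed = stage_seed(0))
rec <- demean_errors(simulate_forecast_errors(wx, counties,
                                              seed = stage_seed(1)),
                     "county")
rec[counties, wfo_id := i.wfo_id, on = "county_id"]
popw <- counties$population_base[match(rec$county_id, counties$county_id)]

mean_model <- fit_error_mean(rec, weights = popw)
var_model <- fit_error_variance(rec, mean_model, weights = popw)
pool <- standardize_errors(rec, mean_model, var_model)

cat(sprintf("Variance trend delta = %+.4f per year (SE %.4f): SD changes %.1f%%/yr\n",
            var_model$delta, var_model$delta_se,
            100 * (exp(var_model$delta / 2) - 1)))

bins <- data.table(
  bin_lower = as.numeric(names(pool$bins)),
  n = vapply(pool$bins, length, integer(1)),
  mean_std_error = vapply(pool$bins, mean, numeric(1)),
  sd_std_error = vapply(pool$bins, sd, numeric(1)))
fwrite(bins, "results/standardized_error_pool.csv")
cat(sprintf("Pool: %d bins, standardized means in [%.3f, %.3f], SDs in [%.2f, %.2f]\n",
            nrow(bins), min(bins$mean_std_error), max(bins$mean_std_error),
            min(bins$sd_std_error), max(bins$sd_std_error)))

grid <- data.table(temp = seq(-10, 35, 5))
grid[, `:=`(mean_error = predict_error_mean(mean_model, temp,
                                            rep(counties$wfo_id[1], .N)),
            sd_error = predict_error_sd(var_model, temp,
                                        rep(counties$wfo_id[1], .N),
                                        max(cfg$years)))]
fwrite(grid, "results/error_model_profile.csv")
cat("Wrote results/standardized_error_pool.csv, results/error_model_profile.csv\n")
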