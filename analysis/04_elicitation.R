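#!/usr/bin/env Rscript
# Stage 4 — expert elicitation of future forecast accuracy.
#
# Simulates expert percentile responses (best case / median / worst case
# accuracy for 2050 and 2100, some experts reporting MAE or MSE),
# converts everything to RMSE, normalizes to multiplicative changes from
# 2020, calibrates a skew-lognormal to each expert's triplet, pools them
# into an equal-weight mixture, and extracts the 10th/50th/90th
# percentile scenario targets for 2100.

source("analysis/00_config.R")

cfg <- ANALYSIS_CFG
experts <- simulate_expert_responses(cfg$n_experts, seed = stage_seed(3))

# historical (MAE, RMSE) pairs at the office-year level for unit
# conversion; the observed relation is strongly linear
hist_pairs <- data.frame(mae = seq(0.8, 2.0, length.out = 20))
hist_pairs$rmse <- 1.25 * hist_pairs$mae
experts_rmse <- convert_mae_to_rmse(experts, hist_pairs)
changes <- normalize_changes(experts_rmse)

rows_2100 <- which(changes$horizon == 2100)
fits <- lapply(rows_2100, function(i)
  fit_skew_lognormal(changes$chg01[i], changes$chg50[i], changes$chg99[i]))
mixture <- build_mixture(fits)

# alternative: performance weights from the observed 2005-2020 change
w_perf <- performance_weights(changes$chg_2005_2020[rows_2100],
                              observed_change = 0.66, lam = 20)
mixture_perf <- build_mixture(fits, weights = w_perf)

tab <- data.table(
  percentile = c(10, 50, 90),
  change_equal_w = qmix(mixture, c(0.1, 0.5, 0.9)),
  change_perf_w = qmix(mixture_perf, c(0.1, 0.5, 0.9)))
fwrite(tab, "results/elicitation_mixture_quantiles.csv")

cat(sprintf("%d experts (%d reporting MAE, converted via RMSE = a + b MAE)\n",
            cfg$n_experts, sum(experts[horizon == 2100]$metric == "MAE")))
cat(sprintf("2100 RMSE change: accelerated %.2f / central %.2f / slowed %.2f (equal weights)\n",
            tab$change_equal_w[1], tab$change_equal_w[2],
            tab$change_equal_w[3]))
cat(sprintf("Performance weighting shifts the median to %.2f\n",
            tab$change_perf_w[2]))

# annual RMSE trajectory through the central 2100 target
hist_rmse <- setNames(2.0 * 0.977^(0:18), 2005:2023)
path <- extrapolate_accuracy_path(hist_rmse,
                                  hist_rmse["2023"] * tab$change_equal_w[2])
cat(sprintf("Historical rate %.2f%%/yr; central scenario requires %.2f%%/yr to 2100\n",
            100 * path$r_hat, 100 * path$r_star))
fwrite(data.table(year = as.integer(names(path$trajectory)),
                  rmse = as.numeric(path$trajectory)),
       "results/accuracy_trajectory_central.csv")
cat("Wrote results/elicitation_mixture_quantiles.csv, results/accuracy_trajectory_central.csv\n")
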