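# Shared small-scale fixtures, built once per test run.  All synthetic,
# generated in code with fixed seeds.

library(data.table)

.fx_cache <- new.env(parent = emptyenv())

# small county panel with records, truth, mortality, design, and fit
fixture_panel <- function() {
  if (!is.null(.fx_cache$panel)) return(.fx_cache$panel)
  counties <- generate_counties(24, 4, 6, seed = 101)
  wx <- simulate_daily_weather(counties, 2005:2008, seed = 102)
  rec <- simulate_forecast_errors(wx, counties, seed = 103)
  rec <- demean_errors(rec, "county")
  rec[counties, `:=`(wfo_id = i.wfo_id, state_id = i.state_id),
      on = "county_id"]
  truth <- make_truth_surface()
  mort <- simulate_mortality(rec, counties, truth, seed = 104)
  popw <- counties$population_base[match(rec$county_id, counties$county_id)]
  spec <- resolve_knots(rec, basis_spec(), weights = popw)
  design <- aggregate_monthly(rec, mort, counties, spec)
  fit <- fit_panel(design)
  .fx_cache$panel <- list(counties = counties, records = rec, truth = truth,
                          mortality = mort, spec = spec, design = design,
                          fit = fit, popw = popw)
  .fx_cache$panel
}

# a panel_fit-like object carrying an arbitrary coefficient vector, for
# projection tests on planted (noise-free) surfaces
planted_fit <- function(beta, knots, vcov_scale = 1e-8) {
  stopifnot(length(beta) == 13)
  out <- list(beta = beta, se = rep(vcov_scale, 13),
              vcov = diag(vcov_scale^2, 13), knots = knots,
              xcols = paste0("x", 1:13), n_obs = NA, n_clusters = NA)
  class(out) <- "panel_fit"
  out
}

# noise-free truth: all nuisance components and noise switched off
noiseless_truth <- function(...) {
  make_truth_surface(fe_scale_county_month = 0, fe_scale_state_time = 0,
                     trend_scale = 0, noise_sd = 0, rain_coef = 0, ...)
}

expect_rel_equal <- function(actual, expected, tol, scale = NULL) {
  s <- scale %||% pmax(abs(expected), 1e-12)
  expect_true(max(abs(actual - expected) / s) < tol)
}
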