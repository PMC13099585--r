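---
title: "Methods: temperature forecast errors, mortality, and scenario projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temperature forecast errors, mortality, and scenario projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foremort)
library(data.table)
```

# The problem

Day-ahead temperature forecasts let people prepare for dangerous heat and
cold. When a forecast misses — the day turns out hotter or colder than
announced — preparation is misallocated and mortality can rise. This
package implements an analysis chain that (i) estimates how daily
mortality depends jointly on realized temperature and on the day-ahead
forecast *error*, (ii) models how the distribution of forecast errors
varies with temperature and improves over time, (iii) turns expert
judgments about future forecast accuracy into probability distributions
and scenario targets, and (iv) combines everything with climate warming
scenarios to project annual lives saved by better forecasts.

Real inputs of this kind (county mortality registers, archived gridded
forecasts and observations, climate-model output) are restricted or very
large. The package therefore ships a first-class synthetic-data module
that generates county panels with the statistical structure the analysis
assumes, from a *known* response surface. Every stage of the chain can
then be validated by parameter recovery at desk scale. That is the
package's central epistemic move: passing tests show the *estimators and
projection machinery* are correct, not that any particular real-world
effect size is true.

# The response-surface model

## Design basis

Daily exposure in county $c$ on day $d$ is summarized by a 13-dimensional
basis $x(T_{cd}, e_{cd})$:

* $x_1..x_4$: a fourth-order polynomial in realized daily-mean
  temperature $T$ (°C);
* $x_5..x_7$: a natural cubic spline in the demeaned day-ahead forecast
  error $e$ = forecast − realization (°C), with internal knots at the
  population-weighted 35th/65th percentiles and boundary knots at the
  5th/95th percentiles of the error distribution;
* $x_8..x_{13}$: the three spline columns interacted with $T$ and $T^2$,
  letting the lethality of a miss depend on how hot or cold the day
  actually was.

The spline uses the truncated-power natural basis $N_1(e) = e$,
$N_{m+1}(e) = d_m(e) - d_3(e)$ with
$d_j(e) = [(e-k_j)^3_+ - (e-k_4)^3_+]/(k_4-k_j)$, which is exactly linear
outside the boundary knots — effects of extreme misses extrapolate
linearly rather than cubically. With 2 internal + 2 boundary knots this
gives 3 columns, and $4 + 3\cdot(1 + 2) = 13$. The basis carries no
intercepts; levels are absorbed by fixed effects.

Errors are demeaned at the county level before entering the basis
(removing persistent offsets between forecast and observation products);
county-month and county-month-temperature-bin demeaning are available as
alternatives. The knot percentiles are computed on the demeaned errors by
default (computing them on raw errors is supported through explicit
numeric knots).

## Estimating equation

Daily basis vectors are summed over days within a county-month,
$X_{ct} = \sum_{d \in t} x(T_{cd}, e_{cd})$, matching the monthly
resolution of mortality registers. Under temporal separability the
monthly regression recovers the daily coefficients exactly (this is a
tested invariant). Aggregating within calendar months also accommodates
roughly two weeks of short-run mortality displacement ("harvesting") on
average. The estimating equation is

$$ m_{ct} = X_{ct}'\beta + g(P_{ct}) + \lambda_{cm} + \alpha_{cm}\,t
   + \rho_{st} + \varepsilon_{ct}, $$

where $m_{ct}$ is the county-month mortality rate per 100,000,
$g(P_{ct})$ is an indicator for county-month precipitation above the
county's own sample median (entered linearly), $\lambda_{cm}$ are
county-by-calendar-month intercepts, $\alpha_{cm} t$ are
county-by-calendar-month linear trends in a consecutive month index
($t = 0$ in the first sample month), and $\rho_{st}$ are
state-by-year-month shocks. Estimation is weighted least squares with
base-year county population weights (fixed, so later migration cannot
move the weights), and standard errors are clustered at the weather
forecast office (WFO) — the unit at which forecasts are produced — using
the one-way sandwich with small-sample factor
$\tfrac{G}{G-1}\tfrac{N-1}{N-K}$, $K$ counting design plus identified
absorbed parameters.

No high-dimensional fixed-effects back end is used: the within
transformation is computed by alternating weighted projections (sweeping
the county-month intercept+trend projection and the state-year-month
mean until convergence, per-column relative tolerance $10^{-13}$). On
instances small enough to run both, the absorbed estimates and the
clustered covariance match an explicit dummy-variable WLS fit with a
brute-force sandwich to $10^{-8}$ relative — a tested acceptance
property. The identified-parameter count $K$ is computed from the cell
structure (county-month cells spanning $\{1,t\}$, plus state-year-month
cells, minus their overlap, which is the span of $\{1,t\}$ within
state-month cells); it equals the `lm()` rank on the same instances.

## Heterogeneity and diagnostics

A robustness variant lets the coefficient vector vary with county
characteristics,
$\beta_c = \bar\beta + \mu^T_c \gamma_T + \sigma^T_c \gamma_\sigma +
\mathrm{RMSE}_c\,\gamma_{RMSE}$, where $\mu^T_c$ is the county's mean
temperature, $\sigma^T_c$ the root-mean-square day-to-day temperature
change (the skill of a persistence forecast), and $\mathrm{RMSE}_c$ the
county's day-ahead forecast accuracy. Characteristics are Winsorized at
their population-weighted 5th/95th percentiles, and any projection with
evolved characteristics is clipped back to that in-sample band. The
joint Wald test of the interaction blocks uses the clustered covariance;
because a one-way cluster covariance has rank at most $G-1$, the test
pseudo-inverts and uses the rank as degrees of freedom when the number
of restrictions exceeds it.

A separate diagnostic residualizes both county-level hot-day excess
mortality from forecast errors (1 °C bins above 20 °C, weighted by
days-per-year in each bin) and air-conditioning take-up on the three
characteristics, trims AC residuals to their 2.5–97.5 percentile range,
drops the four lowest mortality-residual counties, and reports the
residual pairs with a lowess smooth (span 2/3, 3 robustness iterations —
conventional defaults).

# Forecast-error models and future errors

Projection needs future forecast errors consistent with both a changed
climate and a chosen accuracy scenario. Three ingredients:

1. **Conditional mean.** Weighted least squares of the error on a
   natural cubic spline of temperature (boundary knots −15/35 °C,
   internal knots every 5 °C) plus WFO intercepts.
2. **Conditional variance.** A Gamma GLM with log link for the squared
   mean-deviations on the same spline, WFO intercepts, and a linear
   calendar-year trend $\delta$ (log-variance change per year). The log
   link keeps extrapolated variances positive and encodes improvements
   that are proportional — rather than absolute — across the temperature
   range. Starting values come from a log-scale least-squares fit; the
   dispersion is profiled out (it does not affect mean predictions); the
   trend's reported SE is model-based with Pearson dispersion.
3. **Standardized pool.** Historical standardized errors
   $\tilde e = (e - \hat\mu)/\hat\sigma$ are pooled in half-open 5 °C
   bins $[5k, 5k+5)$ of realized temperature (end bins open; a future
   temperature outside the historical support falls back to the nearest
   nonempty bin). The pool preserves conditional skewness and kurtosis
   beyond the first two moments.

A future error is reconstructed as
$e = \hat\mu(T, \mathrm{wfo}) + \hat\sigma(T, \mathrm{wfo}, y)\,\tilde
e^{(b)}$, drawing $\tilde e^{(b)}$ uniformly with replacement from the
day's temperature bin. Standardizing and reconstructing with the same
models is an exact identity (tested to $10^{-10}$). Resampling matches
the conditional SD of errors well; a known limitation is that the
resampled errors carry somewhat too little excess kurtosis in the
extreme hot bins, which makes projected benefits conservative there.

Accuracy scenarios modify only the post-sample trend: within the sample
the fitted $\delta$ applies, and from the last sample year forward a
scenario trend $\delta'$ is used. $\delta'$ is calibrated so the
population-weighted national RMSE implied over the end-century climate
panel — $\sqrt{\mathrm{wmean}(\hat\sigma^2 + \hat\mu^2)}$, measured about
zero so conditional bias counts against accuracy — equals the scenario
target; the implied RMSE is strictly increasing in $\delta'$, so
bracketed root finding yields the unique solution (residual under
$10^{-6}$ °C, with a single-county closed form used as a test oracle).
The `constant` scenario freezes the SD at its end-of-sample level
($\delta' = 0$), and `zero_error` generates no errors at all (the
perfect-forecast bound).

# Expert elicitation

Experts report their preferred accuracy metric (MSE, RMSE, or MAE), 2005
and 2020 accuracy, and best-case/median/worst-case accuracy (1st, 50th,
99th percentiles) for 2050 and 2100. MSE responses map to RMSE by square
root; MAE responses via an OLS line fitted to historical office-year
(MAE, RMSE) pairs, which are strongly linear. Each expert's horizon
accuracies are normalized by their 2020 report, giving percentile
triplets of the *multiplicative* RMSE change (values above 1 — expected
degradation — are allowed).

Each triplet is calibrated to a skew-lognormal distribution, concretized
as $\exp(\xi + \omega Z_\alpha)$ with $Z_\alpha$ standard skew-normal:
strictly positive, with tunable asymmetry. The three equations reduce,
on the log scale, to a one-dimensional root in $\alpha$ via the
quantile-spacing ratio, after which $\omega$ and $\xi$ are closed-form;
feasible triplets are reproduced to $10^{-6}$ relative. The skew-normal
spacing ratio is bounded (about 2.9 at $|\alpha| \to \infty$), so
triplets more asymmetric than that get the nearest-feasible boundary fit
with the median preserved and a diagnostic flag. The skew-normal CDF is
computed via Owen's T function (adaptive quadrature) and inverted by
root finding.

Experts are pooled as a mixture $F = \sum_i w_i F_i$ with equal weights
by default (no prior information favours an expert); an alternative
weights experts by how well their reported 2005–2020 change matches the
observed one, $w_i \propto \exp(-\lambda (y_i - y_{obs})^2)$ with
$\lambda = 20$. Scenario targets scale the observed 2020 base RMSE by
mixture quantiles: accelerated = 10th percentile of the change
(most improvement), central = median, slowed = 90th. Annual
trajectories fit a constant annual percentage change to the historical
RMSE series (least squares on log first differences, which keeps
extrapolations positive) and rescale that rate so the path passes
exactly through the 2100 target; 2050 responses are fitted but
trajectories are anchored only at 2100. Experts elicited on 3-day-ahead
accuracy are applied to 1-day-ahead changes unchanged, assuming
short-range horizons improve at similar percentage rates.

# Projection

Climate paths are bias-adjusted by county: quadratic-in-year trends are
fitted to observed and projected annual mean temperatures, both predicted
at a common anchor year, and the difference subtracted from all projected
daily temperatures.

The minimum mortality temperature (MMT) is the temperature in
[10, 35] °C minimizing the fitted surface at zero error (0.1 °C grid
plus local refinement; ties break toward the lower temperature). Under
heterogeneity, counties whose surface has no interior minimum take a
29.5 °C cap, and all MMTs are capped there. Daily excess mortality is
$\widehat{em}(T, e) = \hat f(T, e) - \hat f(\mathrm{MMT}, 0)$ — exactly
zero at the optimum and linear in the coefficients. Deaths are rate ×
base-year population / 100,000, summed to years and averaged over
six-year windows (2015–2020 reference, 2095–2100 evaluation by default)
to damp idiosyncratic years; hot-day totals gate on realized projected
temperature strictly above 20 °C.

Lives saved by an accuracy scenario are the constant-scenario deaths
minus the scenario deaths on the same climate panel (the standardized
draws reuse common random numbers across scenarios, so differences are
not noised by resampling). 95% CIs propagate regression-coefficient
uncertainty only — draws from $N(\hat\beta, \hat V_{cluster})$
re-evaluate both projections, re-searching the MMT per draw; error-model
and elicitation uncertainty are deliberately not propagated, a
documented limitation. Because annual deaths are linear in the
coefficients given the MMT, each projection stores aggregate basis sums
and the re-evaluation is a dot product, which keeps 1,000 draws cheap.

# The synthetic study

The generator emulates, with known parameters:

* **Weather:** county daily mean temperature = climatological mean +
  seasonal sinusoid (peak mid-July) + stationary AR(1) noise
  (coefficient 0.7); wet-day Bernoulli × Gamma precipitation.
* **Forecast errors:** conditional mean decreasing through ~20 °C
  (forecasts run warm on cold days, cool on hot days), SD declining in
  temperature and by −2.3%/year (consistent with roughly a one-third
  RMSE improvement over two decades), right skew when cold / left skew
  when hot via a skew-normal shock, and excess kurtosis on days above
  25 °C via a variance-preserving two-point scale mixture — chosen over
  a named heavy-tailed family because its moments are controllable in
  closed form.
* **Mortality:** monthly rate = summed basis × a planted 13-coefficient
  truth + rainfall term + county-month effects + county-month trends +
  state-year-month shocks + noise, all i.i.d. normal with configurable
  scales (any fixed pattern would be absorbed; randomness stress-tests
  the within-estimator). Daily mortality stays latent; only monthly sums
  are emitted, mirroring the observed-data constraint. The truth surface
  plants a U-shaped temperature curve (quartic vertex near 25 °C; the
  spline columns at $e=0$ shift the realized MMT to ≈22.5 °C) and a
  convex error response whose slope at $e = 0$ is cancelled within each
  interaction block, so zero error is optimal at every temperature.
  Magnitudes are calibrated so a ~3 °C miss on a hot (32 °C) day
  contributes ≈0.5 deaths per 100,000 per day — the order of magnitude
  published temperature-mortality studies report for hot-day forecast
  errors — and a 0 °C day carries ≈0.4 excess deaths per 100,000 per day
  relative to the MMT.
* **Experts:** percentile triplets are exact quantiles of known
  skew-lognormal change laws (median change ≈0.5 by 2100, right skew
  including degradation), with a configurable share reporting MAE under
  a known linear RMSE relation.
* **Climate scenarios:** the no-change scenario copies reference-period
  temperatures to the evaluation years; warming scenarios add a linear
  ramp reaching the target delta at end-century.

What the generator does *not* emulate: spatial correlation of errors
across counties within a day (draws are independent given temperature
bins), gridded raster structure, population dynamics (weights stay at
base year), suppression mechanics beyond state-rate imputation of
flagged county-months, and non-Gaussian nuisance effects. Passing tests
therefore validate estimator correctness and calibration under these
conditions — not the magnitude of any real-world effect, nor robustness
to confounding structures the generator does not contain.

## Problem sizes and numerical choices

The default validation panel is 200 counties in 20 states and 20 WFOs
(10 counties per office — enough clusters for the $t_{G-1}$ tails that
clustered inference needs) over 10 years of daily data: ~730k
county-days aggregating to 24k county-months. The parameter-recovery
study runs 20 replicates at these conditions: the planted 13-vector is
recovered within 3 clustered SEs componentwise, and pooled 95% CI
coverage (with $t_{G-1}$ critical values) stays above 90%. The analysis
drivers use a 100-county, 8-year panel; unit tests use 24 counties over
4 years. Monte-Carlo moment checks use $10^5$–$4\times10^5$ draws so
stated tolerances sit several standard errors away.

Other numerical conventions: alternating-projection tolerance
$10^{-13}$ per column (sup norm, capped at 5,000 sweeps); MMT grid
0.1 °C with `optimize` refinement; skew-normal shape search bounded at
$|\alpha| \le 50$; mixture quantiles by bracketed root finding on the
CDF; scenario-trend root finding with adaptive bracket expansion;
degenerate inputs (collinear columns, single clusters, all-suppressed
state-months, empty pools, non-monotone knots or percentile triplets)
are refused with informative errors rather than patched.

## Design choices that were genuinely open

* The spline parameterization (the field names the spline type, not the
  basis): fixed to the truncated-power natural basis above so the
  4 + 9 column split is exact and reproducible.
* Rainfall control: one linear indicator against the county's own
  sample median (state or national medians would also be defensible;
  the county median keeps the control within-county like the fixed
  effects).
* $t$ in the county-month trend: a consecutive month index starting at
  0, interacted with county-calendar-month cells.
* RMSE measured about zero rather than about $\hat\mu$, so conditional
  bias counts as inaccuracy (switchable).
* Standardization uses model-based $\hat\sigma$ (with the in-sample
  trend) rather than year-specific empirical SDs.
* The elicitation calibration matches the three reported percentiles
  exactly rather than moments; a moment-matching alternative would be a
  config-level change.
* State-year-month effects subsume a national year-month effect by
  construction here.
* The `pipeline_cli` surface is the set of numbered scripts under
  `analysis/` plus `run_pipeline()`; the package is an analysis chain,
  not a shell tool, so no separate command-line wrapper is provided.

## Known limitations

CIs understate total uncertainty (coefficient uncertainty only).
Cluster-robust inference with moderate cluster counts has mildly heavy
tails; the recovery study quantifies this rather than hiding it.
Resampled future errors under-represent extreme-bin kurtosis. The
heterogeneity model is linear in characteristics and its cross-county
contrasts are associational, not causal. Lives-saved magnitudes from the
synthetic study are properties of the planted surface and synthetic
population, not of any real population.
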