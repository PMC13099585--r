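# foremort

Estimating how daily temperature and day-ahead **forecast errors**
jointly affect mortality, and projecting the **lives saved by better
weather forecasts** under climate-warming scenarios.

## The scientific problem

Accurate day-ahead temperature forecasts let people prepare for
dangerous heat and cold. When the forecast misses — the day turns out
hotter or colder than announced — that preparation is misallocated, and
mortality can rise. Quantifying this requires a response surface in
*two* arguments: realized temperature $T$ and the forecast error
$e$ = forecast − realization. This package implements the full analysis
chain for that question:

1. **Response surface.** A 13-column daily basis — a 4th-order
   polynomial in $T$, a 3-column natural cubic spline in the
   county-demeaned error $e$ (internal knots at the population-weighted
   35th/65th percentiles, boundary knots at the 5th/95th), and the
   spline interacted with $T$ and $T^2$ — summed to county-months and
   fitted by weighted fixed-effects regression:

   $$ m_{ct} = X_{ct}'\beta + g(P_{ct}) + \lambda_{cm} + \alpha_{cm} t
      + \rho_{st} + \varepsilon_{ct}, $$

   with county-month intercepts and trends, state-year-month shocks, a
   rainfall control, base-year population weights, and standard errors
   clustered at the weather forecast office (WFO). The within
   transformation is computed by alternating weighted projections and
   verified against explicit dummy-variable least squares.

2. **Forecast-error models.** The conditional mean of errors is a spline
   in temperature plus WFO intercepts; the conditional variance is a
   Gamma GLM (log link) with an annual trend $\delta$. Standardized
   errors are pooled in 5 °C temperature bins and resampled to generate
   future errors $e = \hat\mu + \hat\sigma\,\tilde e$ that preserve
   conditional skewness and kurtosis.

3. **Expert elicitation.** Expert best/median/worst-case accuracy
   percentiles for 2100 are calibrated to skew-lognormal distributions,
   pooled into a mixture, and turned into *slowed / central /
   accelerated* RMSE scenarios; the variance-model trend is re-solved so
   each scenario's implied national RMSE hits its target.

4. **Projection.** Excess mortality
   $\widehat{em}(T,e) = \hat f(T,e) - \hat f(\mathrm{MMT}, 0)$ relative
   to the minimum mortality temperature, scaled by population, summed to
   years, averaged over six-year windows, and differenced across
   forecast scenarios to get lives saved, with CIs from the clustered
   coefficient covariance.

Because the real inputs (mortality registers, forecast archives, climate
grids) are restricted or huge, the package ships a **synthetic-data
module**: county panels with seasonal AR(1) weather, forecast errors
whose mean/SD/skew/kurtosis vary with temperature and improve over time,
and mortality generated from a *known* response surface. Every stage is
validated by parameter recovery against that planted truth.

**Who this is for:** environmental epidemiologists and climate-economics
researchers who want a tested, reusable implementation of this analysis
chain — to run on their own county panels, or to study the estimators'
behavior under controlled conditions.

## Worked example

The numbered scripts under `analysis/` run the chain on a 100-county,
8-year synthetic panel (all computation lives in package functions):

```sh
Rscript analysis/01_simulate.R     # synthetic county panel
Rscript analysis/02_fit_panel.R    # design + fixed-effects fit
Rscript analysis/03_error_models.R # conditional error models + pool
Rscript analysis/04_elicitation.R  # expert mixture + scenario targets
Rscript analysis/05_project.R      # lives saved with CIs
```

Stage 2 prints (abridged):

```
Error-spline knots (weighted pctiles 5/35/65/95): -2.48, -0.61, +0.49, +2.73 C
Fitted 9,600 county-months, 12 WFO clusters, K = 3134 absorbed+design params
Recovery: max |z| vs planted truth = 2.71 (all 13 within 3 SE: TRUE)
Fitted MMT 22.12 C (planted 22.49 C)
```

The knots are where the demeaned error distribution puts its 5/35/65/95
weighted percentiles; the planted 13-coefficient truth is recovered
within sampling error, and the fitted minimum mortality temperature
(22.1 °C) sits next to the planted one (22.5 °C).

Stage 5 prints:

```
Fitted MMT: 22.12 C; base 2020 RMSE 1.47 C
Six-year mean annual lives saved vs constant forecast accuracy (all days):
   climate_scenario accelerated central slowed zero_error
1:             high         801     545 -17.98       1160
2:         moderate         802     551   3.39       1145
3:        no_change         814     572  51.80       1125
Hot-day (>20 C) share of central-scenario savings:
   climate_scenario hot_share
1:             high      0.44
2:         moderate      0.40
3:        no_change      0.33
```

Reading this: on the synthetic population, the central accuracy scenario
(expert-median RMSE improvement to 2100) averts ~550–570 deaths per year
relative to frozen accuracy, and a perfect day-ahead forecast would
avert ~1,100–1,200; the slowed scenario barely improves on constant
accuracy, so its savings are near zero. The share of savings coming from
hot days (>20 °C) rises with the warming scenario — better forecasts
matter most where climate change makes heat more common. These
magnitudes describe the planted synthetic surface, not any real
population.

The same chain is callable in R:

```r
library(foremort)
res <- run_pipeline(pipeline_config(n_counties = 40, years = 2005:2010),
                    seed = 42)
res$targets          # elicited 2100 RMSE scenarios
res$lives_saved      # lives saved per climate x forecast scenario, with CIs
```

## Package layout

| Path | Contents |
| --- | --- |
| `R/synthdata.R` | synthetic counties, weather, forecast errors, mortality, experts, climate scenarios |
| `R/basis.R` | demeaning, knot resolution, natural-spline basis, 13-column design, monthly aggregation |
| `R/panelfit.R` | within-estimator, clustered sandwich, heterogeneity, AC diagnostic |
| `R/errorproj.R` | conditional mean/variance models, standardized pool, scenario calibration, future draws |
| `R/elicitation.R` | skew-lognormal calibration, mixtures, performance weights, accuracy trajectories |
| `R/projection.R` | bias adjustment, MMT, excess mortality, lives saved with CIs |
| `R/pipeline.R` | `pipeline_config()` / `run_pipeline()` orchestration |
| `analysis/` | numbered narrative drivers writing `results/*.csv` |
| `vignettes/forecast-mortality-methods.Rmd` | the methods vignette: models, assumptions, parameter choices, limitations |

See the methods vignette for the model details, every tunable parameter
with its default and rationale, what the synthetic generator does and
does not emulate, and known limitations.
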