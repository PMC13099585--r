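# Combining the fitted response surface, climate paths, and scenario error
# draws into annual excess mortality, hot-day mortality, and lives saved
# with coefficient-uncertainty confidence intervals.

#' Bias-adjust a projected climate panel against observations
#'
#' Fits county-specific quadratic-in-year trends to observed and projected
#' annual mean temperatures, predicts both at a common anchor year, and
#' subtracts the difference (projected minus observed) from every
#' projected daily temperature.
#'
#' @param observed_annual county-year `data.table` with `county_id`,
#'   `year`, `mean_temp` from observations.
#' @param projected_annual same structure from the climate model.
#' @param projected_daily county-day panel to adjust (column `temp`).
#' @param anchor_year year at which both trends are compared (default: the
#'   first projected year).
#' @return the adjusted daily panel, with the per-county adjustment in
#'   attribute `"bias_adjustment"`.
#' @export
bias_adjust_climate <- function(observed_annual, projected_annual,
                                projected_daily, anchor_year = NULL) {
  ob <- as.data.table(observed_annual)
  pr <- as.data.table(projected_annual)
  anchor_year <- anchor_year %||% min(pr$year)
  if (uniqueN(ob$year) < 3 || uniqueN(pr$year) < 3)
    stop("need >= 3 years in each series for a quadratic trend")
  quad_pred <- function(y, v, at) {
    cf <- coef(lm(v ~ y + I(y^2)))
    as.numeric(cf[1] + cf[2] * at + cf[3] * at^2)
  }
  adj <- merge(
    ob[, .(obs_at = quad_pred(year, mean_temp, anchor_year)), by = county_id],
    pr[, .(prj_at = quad_pred(year, mean_temp, anchor_year)), by = county_id],
    by = "county_id")
  adj[, adjustment := prj_at - obs_at]
  out <- as.data.table(copy(projected_daily))
  out[adj, temp := temp - i.adjustment, on = "county_id"]
  setattr(out, "bias_adjustment", adj[, .(county_id, adjustment)])
  out[]
}

#' Find the minimum mortality temperature (MMT)
#'
#' Grid search at 0.1 deg C over \[10, 35\] of the fitted surface at zero
#' forecast error, refined locally by `optimize`; ties break toward the
#' lower temperature.  Under a heterogeneous response, counties whose
#' surface attains no interior minimum (argmin at the hot boundary) are
#' assigned the cap (29.5 deg C by default), and all MMTs are capped
#' there.
#'
#' @param fit a `panel_fit` or `het_panel_fit`.
#' @param characteristics per-county characteristics for heterogeneous
#'   fits.
#' @param range search range, default `c(10, 35)`.
#' @param cap MMT cap applied under heterogeneity (default 29.5).
#' @return MMT in deg C.
#' @export
find_mmt <- function(fit, characteristics = NULL, range = c(10, 35),
                     cap = 29.5) {
  grid <- seq(range[1], range[2], by = 0.1)
  v <- predict_surface(fit, grid, rep(0, length(grid)), characteristics)
  i <- which.min(v)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  op <- optimize(function(tt) predict_surface(fit, tt, 0, characteristics),
                 c(lo, hi), tol = 1e-6)
  mmt <- if (op$objective < v[i]) op$minimum else grid[i]
  if (inherits(fit, "het_panel_fit")) {
    if (mmt >= range[2] - 0.1) mmt <- cap   # no interior minimum
    mmt <- min(mmt, cap)
  }
  mmt
}

#' Build a response function for projection
#'
#' Bundles a fitted surface with (optionally evolved) per-county
#' characteristics and per-county MMTs.
#'
#' @param fit a `panel_fit` or `het_panel_fit`.
#' @param characteristics county characteristics table (required for
#'   heterogeneous fits).
#' @param county_ids counties to cover; defaults to the characteristics
#'   table (homogeneous fits may pass any set).
#' @param mmt_cap cap under heterogeneity.
#' @return object of class `response_function` with `fit`, `mmt` (named
#'   per county, or a single shared value), `chars`.
#' @export
make_response_function <- function(fit, characteristics = NULL,
                                   county_ids = NULL, mmt_cap = 29.5) {
  if (inherits(fit, "het_panel_fit")) {
    stopifnot(!is.null(characteristics))
    ch <- as.data.table(characteristics)
    ids <- county_ids %||% ch$county_id
    mmt <- vapply(ids, function(cid)
      find_mmt(fit, ch[county_id == cid], cap = mmt_cap), numeric(1))
    names(mmt) <- ids
  } else {
    mmt <- find_mmt(fit)
    ch <- NULL
  }
  out <- list(fit = fit, mmt = mmt, chars = if (is.null(characteristics))
    NULL else as.data.table(characteristics), mmt_cap = mmt_cap)
  class(out) <- "response_function"
  out
}

#' Daily excess mortality rate
#'
#' em(T, e) = f_c(T, e) - f_c(MMT_c, 0): the fitted mortality-rate
#' contribution at the day's temperature and forecast error minus its
#' value at the county's minimum mortality temperature with a perfect
#' forecast.  Exactly zero at (MMT, 0) and linear in the coefficient
#' vector.
#'
#' @param response a [make_response_function()] object.
#' @param county a county id (scalar).
#' @param temp,e numeric vectors.
#' @return deaths per 100,000 per day.
#' @export
excess_mortality_rate <- function(response, county, temp, e) {
  ch <- if (is.null(response$chars)) NULL else
    response$chars[county_id == county]
  m <- if (length(response$mmt) > 1) response$mmt[[county]] else response$mmt
  predict_surface(response$fit, temp, e, ch) -
    predict_surface(response$fit, m, 0, ch)
}

#' Evolve county characteristics to end-century values
#'
#' Applies the scenario-implied percentage change between a baseline
#' period and an end-century period to the observed in-sample
#' characteristic, then clips to the in-sample population-weighted
#' 5th-95th percentile band (preventing far out-of-sample extrapolation of
#' the linear heterogeneity).
#'
#' @param chars_current observed characteristics table (values to evolve).
#' @param chars_baseline,chars_endcentury same-structure tables for the
#'   scenario baseline and end-century periods.
#' @param dims characteristic columns to evolve.
#' @param bands named list of in-sample clip bands (lo, hi) per dim;
#'   defaults to the `"band"` attribute of each `chars_current` column.
#' @return evolved characteristics table.
#' @export
evolve_characteristics <- function(chars_current, chars_baseline,
                                   chars_endcentury,
                                   dims = c("mu_T", "sigma_T", "rmse_c"),
                                   bands = NULL) {
  cur <- as.data.table(copy(chars_current))
  bas <- as.data.table(chars_baseline)
  end <- as.data.table(chars_endcentury)
  for (d in dims) {
    band <- bands[[d]] %||% attr(chars_current[[d]], "band")
    b <- bas[[d]][match(cur$county_id, bas$county_id)]
    e <- end[[d]][match(cur$county_id, end$county_id)]
    if (any(b == 0 & e != 0, na.rm = TRUE))
      stop("zero baseline characteristic ", d,
           " with nonzero end-century value; cannot form a percentage change")
    v <- cur[[d]] * (e / b)
    if (!is.null(band)) v <- pmin(pmax(v, band[1]), band[2])
    set(cur, j = d, value = v)
  }
  cur
}

# per-county-year aggregation of the basis for draw-based inference:
# deaths(beta) = [sum over days of pop/1e5 * z(T, e)] . theta
#              - [days * pop/1e5] * z(mmt_c, 0) . theta
# where z is the (possibly characteristic-augmented) basis row, linear in
# the stacked coefficient vector theta
.augment_basis <- function(X, fit, ch) {
  if (!inherits(fit, "het_panel_fit")) return(X)
  out <- X
  for (d in fit$dims) out <- cbind(out, X[, 1:13] * as.numeric(ch[[d]]))
  out
}

.theta <- function(fit) {
  if (inherits(fit, "het_panel_fit"))
    unname(fit$coef_all[fit$xcols]) else unname(fit$beta)
}

#' Annual excess mortality from a climate-and-error panel
#'
#' Converts daily excess mortality rates into deaths
#' (rate x population / 100,000), sums to the year, and also reports the
#' hot-day subset (realized temperature strictly above the threshold).
#' Returns aggregate basis sums that make the totals a linear function of
#' the coefficient vector, enabling fast re-evaluation under coefficient
#' draws in [lives_saved()].
#'
#' @param panel county-day panel with `temp` and `error` (from
#'   [sample_future_errors()]).
#' @param response a [make_response_function()] object.
#' @param populations named vector of base-year county populations.
#' @param hot_threshold hot-day threshold in deg C (strict, default 20).
#' @return object of class `mortality_projection`: `annual` table
#'   (`year`, `deaths`, `deaths_hot`), `six_year_mean`,
#'   `six_year_mean_hot`, and internal aggregates.
#' @export
annual_excess_mortality <- function(panel, response, populations,
                                    hot_threshold = 20) {
  cp <- as.data.table(panel)
  stopifnot(all(c("temp", "error", "county_id", "date") %in% names(cp)))
  fit <- response$fit
  ids <- sort(unique(cp$county_id))
  if (!all(ids %in% names(populations)))
    stop("populations missing for some counties")
  spec <- basis_spec(knots = fit$knots)
  X <- build_daily_basis(cp$temp, cp$error, spec)
  # per-row population scaling
  popw <- populations[cp$county_id] / 1e5
  yr <- year(cp$date)
  hot <- cp$temp > hot_threshold
  # characteristic augmentation per row (county-level)
  if (inherits(fit, "het_panel_fit")) {
    ch <- response$chars
    Z <- X
    for (d in fit$dims)
      Z <- cbind(Z, X[, 1:13] * ch[[d]][match(cp$county_id, ch$county_id)])
  } else Z <- X
  agg_all <- rowsum(Z * popw, yr)
  agg_hot <- rowsum(Z[hot, , drop = FALSE] * popw[hot],
                    yr[hot], reorder = TRUE)
  # baseline term: per county-year day counts (weighted by pop) at the MMT
  base_cy <- data.table(county_id = cp$county_id, year = yr,
                        w = popw, hot = hot)
  nb <- base_cy[, .(n_w = sum(w), n_w_hot = sum(w[hot])),
                by = .(county_id, year)]
  # per-county basis row at (mmt, 0), augmented
  zb <- lapply(ids, function(cid) {
    m <- if (length(response$mmt) > 1) response$mmt[[cid]] else response$mmt
    Xb <- build_daily_basis(m, 0, spec)
    chc <- if (is.null(response$chars)) NULL else
      response$chars[county_id == cid]
    .augment_basis(Xb, fit, chc)
  })
  names(zb) <- ids
  years <- sort(unique(yr))
  base_all <- matrix(0, length(years), ncol(Z),
                     dimnames = list(years, NULL))
  base_hot <- base_all
  for (cid in ids) {
    sub <- nb[county_id == cid]
    iy <- match(sub$year, years)
    base_all[iy, ] <- base_all[iy, ] + outer(sub$n_w, zb[[cid]][1, ])
    base_hot[iy, ] <- base_hot[iy, ] + outer(sub$n_w_hot, zb[[cid]][1, ])
  }
  theta <- .theta(fit)
  agg_hot_full <- matrix(0, length(years), ncol(Z),
                         dimnames = list(years, NULL))
  agg_hot_full[rownames(agg_hot), ] <- agg_hot
  deaths <- as.numeric((agg_all - base_all) %*% theta)
  deaths_hot <- as.numeric((agg_hot_full - base_hot) %*% theta)
  out <- list(
    annual = data.table(year = years, deaths = deaths,
                        deaths_hot = deaths_hot),
    six_year_mean = mean(deaths),
    six_year_mean_hot = mean(deaths_hot),
    agg = list(all = agg_all, hot = agg_hot_full,
               base_all = base_all, base_hot = base_hot,
               county_base = zb, county_days = nb),
    response = response, hot_threshold = hot_threshold)
  class(out) <- "mortality_projection"
  out
}

# precompute the augmented basis on the MMT search grid; shared across
# counties for a homogeneous fit, per-county under heterogeneity
.mmt_grid <- function(response, county_ids, range = c(10, 35), by = 0.1) {
  fit <- response$fit
  grid <- seq(range[1], range[2], by = by)
  X0 <- build_daily_basis(grid, rep(0, length(grid)),
                          basis_spec(knots = fit$knots))
  if (!inherits(fit, "het_panel_fit"))
    return(list(grid = grid, shared = TRUE, Z = X0))
  Z <- lapply(county_ids, function(cid)
    .augment_basis(X0, fit, response$chars[county_id == cid]))
  names(Z) <- county_ids
  list(grid = grid, shared = FALSE, Z = Z)
}

# re-evaluate mean annual deaths under a coefficient draw, re-searching the
# MMT for the drawn surface
.deaths_under_theta <- function(proj, theta, grid_Z0) {
  ids <- names(proj$agg$county_base)
  years <- proj$annual$year
  base_all <- matrix(0, length(years), length(theta))
  base_hot <- base_all
  nb <- proj$agg$county_days
  if (grid_Z0$shared) {
    zrow <- grid_Z0$Z[which.min(grid_Z0$Z %*% theta), ]
    tot <- nb[, .(n_w = sum(n_w), n_w_hot = sum(n_w_hot)), by = year]
    iy <- match(tot$year, years)
    base_all[iy, ] <- outer(tot$n_w, zrow)
    base_hot[iy, ] <- outer(tot$n_w_hot, zrow)
  } else {
    for (cid in ids) {
      Zc <- grid_Z0$Z[[cid]]
      zrow <- Zc[which.min(Zc %*% theta), ]
      sub <- nb[county_id == cid]
      iy <- match(sub$year, years)
      base_all[iy, ] <- base_all[iy, ] + outer(sub$n_w, zrow)
      base_hot[iy, ] <- base_hot[iy, ] + outer(sub$n_w_hot, zrow)
    }
  }
  c(all = mean((proj$agg$all - base_all) %*% theta),
    hot = mean((proj$agg$hot - base_hot) %*% theta))
}

#' County-level hot-day excess mortality from forecast errors
#'
#' For each county, the error-attributable excess rate
#' f_c(T, e) - f_c(T, 0) is averaged within 1 deg C bins of realized
#' temperature above the threshold and combined across bins weighted by
#' the county's days-per-year count in each bin.  This is the mortality
#' measure used in the air-conditioning residualization diagnostic.
#'
#' @param response a [make_response_function()] object.
#' @param records historical county-day records with `temp` and
#'   `error_demeaned`.
#' @param threshold hot-day threshold (strict, deg C).
#' @return named numeric vector (county id -> rate per 100,000 per day).
#' @export
hot_day_error_mortality <- function(response, records, threshold = 20) {
  rec <- as.data.table(records)[temp > threshold]
  n_years <- uniqueN(year(rec$date))
  out <- rec[, {
    cid <- .BY$county_id
    ch <- if (is.null(response$chars)) NULL else
      response$chars[county_id == cid]
    em <- predict_surface(response$fit, temp, error_demeaned, ch) -
      predict_surface(response$fit, temp, 0, ch)
    bin <- floor(temp)
    bs <- data.table(em = em, bin = bin)[, .(m = mean(em), n = .N), by = bin]
    .(value = weighted.mean(bs$m, bs$n / n_years))
  }, by = county_id]
  setNames(out$value, out$county_id)
}

#' Lives saved by a forecast-accuracy scenario, with CIs
#'
#' Point estimate: six-year-average annual excess deaths under the
#' baseline (constant-accuracy) forecast scenario minus those under the
#' improvement scenario, on the same climate panel.  The 95% CI propagates
#' regression-coefficient uncertainty only: both projections are
#' re-evaluated under draws from N(beta_hat, V_clustered) (common random
#' numbers across scenarios), re-searching the MMT for each draw, and the
#' 2.5/97.5 percentiles of the difference are reported.
#'
#' @param proj_scenario,proj_baseline `mortality_projection` objects
#'   computed with the same response and climate panel.
#' @param fit the `panel_fit` whose covariance drives the CI (defaults to
#'   the response's fit).
#' @param n_draws number of coefficient draws (default 1000).
#' @param seed integer seed.
#' @return `data.table` rows for metrics `all_days` and `hot_days`:
#'   `lives_saved`, `lo95`, `hi95`.
#' @export
lives_saved <- function(proj_scenario, proj_baseline, fit = NULL,
                        n_draws = 1000L, seed = 1L) {
  stopifnot(inherits(proj_scenario, "mortality_projection"),
            inherits(proj_baseline, "mortality_projection"))
  if (!isTRUE(all.equal(proj_scenario$agg$county_days,
                        proj_baseline$agg$county_days)))
    stop("climate panels mismatch between scenario and baseline ",
         "(county-day structure differs)")
  fit <- fit %||% proj_scenario$response$fit
  point <- c(all = proj_baseline$six_year_mean - proj_scenario$six_year_mean,
             hot = proj_baseline$six_year_mean_hot -
               proj_scenario$six_year_mean_hot)
  theta_hat <- .theta(fit)
  V <- if (inherits(fit, "het_panel_fit")) fit$vcov else fit$vcov
  if (anyNA(V)) {
    ci <- matrix(NA_real_, 2, 2)
  } else {
    draws <- with_seed(seed,
      MASS::mvrnorm(n_draws, mu = theta_hat, Sigma = V))
    g1 <- .mmt_grid(proj_scenario$response,
                    names(proj_scenario$agg$county_base))
    diffs <- matrix(NA_real_, n_draws, 2)
    for (b in seq_len(n_draws)) {
      th <- draws[b, ]
      d_s <- .deaths_under_theta(proj_scenario, th, g1)
      d_b <- .deaths_under_theta(proj_baseline, th, g1)
      diffs[b, ] <- d_b - d_s
    }
    ci <- apply(diffs, 2, quantile, c(0.025, 0.975))
  }
  data.table(metric = c("all_days", "hot_days"),
             lives_saved = unname(point),
             lo95 = ci[1, ], hi95 = ci[2, ])
}
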