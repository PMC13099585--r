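# Weighted fixed-effects estimation of the mortality response surface.
# Absorbed effects: county-by-calendar-month intercepts, county-by-
# calendar-month linear trends in the consecutive month index, and
# state-by-year-month intercepts.  Standard errors are clustered at the
# weather forecast office (WFO).  No high-dimensional-FE back end is used;
# the within transformation is computed by alternating weighted
# projections (method of alternating projections), which converges to the
# joint projection and is immune to collinearity among the absorbed
# groups.

#' County climate and forecast-skill characteristics
#'
#' mu_T = mean realized temperature; sigma_T = root-mean-square day-to-day
#' temperature change over adjacent days (the RMSE of a naive persistence
#' forecast); rmse_c = root-mean-square day-ahead forecast error (about
#' zero, so bias counts against accuracy).
#'
#' @param records county-day records with `temp`, `forecast`, `date`.
#' @return `data.table` with `county_id`, `mu_T`, `sigma_T`, `rmse_c`, and
#'   an `n_adjacent` count (counties with < 1 adjacent-day pair have
#'   `sigma_T = NA`).
#' @export
compute_county_characteristics <- function(records) {
  rec <- as.data.table(records)
  setkey(rec, county_id, date)
  rec[, dT := temp - shift(temp), by = county_id]
  rec[, adj := as.integer(date - shift(date)) == 1L, by = county_id]
  out <- rec[, .(
    mu_T = mean(temp),
    sigma_T = sqrt(mean(dT[which(adj)]^2)),
    n_adjacent = sum(adj, na.rm = TRUE),
    rmse_c = sqrt(mean((temp - forecast)^2))
  ), by = county_id]
  rec[, c("dT", "adj") := NULL]
  out[n_adjacent == 0, sigma_T := NA_real_]
  out[]
}

# one sweep of the alternating projection: residualize the columns of M on
# (intercept, trend) within cm cells, then on intercepts within st cells,
# all weighted
.sweep_fe <- function(M, w, cm, tindex, st) {
  wt <- w * tindex
  Sw <- as.vector(rowsum(w, cm))
  St <- as.vector(rowsum(wt, cm))
  Stt <- as.vector(rowsum(wt * tindex, cm))
  Sy <- rowsum(w * M, cm)
  Sty <- rowsum(wt * M, cm)
  det <- Sw * Stt - St^2
  ok <- det > 1e-10 * pmax(Sw * Stt, .Machine$double.xmin)
  b <- matrix(0, nrow(Sy), ncol(Sy))
  if (any(ok))
    b[ok, ] <- (Sw[ok] * Sty[ok, , drop = FALSE] -
                  St[ok] * Sy[ok, , drop = FALSE]) / det[ok]
  a <- (Sy - St * b) / Sw
  idx <- match(cm, rownames(Sy))
  M <- M - a[idx, , drop = FALSE] - b[idx, , drop = FALSE] * tindex
  Sw2 <- as.vector(rowsum(w, st))
  Sy2 <- rowsum(w * M, st) / Sw2
  M - Sy2[match(st, rownames(Sy2)), , drop = FALSE]
}

# joint within transformation by alternating projections
.demean_fe <- function(M, w, cm, tindex, st, tol = 1e-13, maxit = 5000L) {
  col_scale <- pmax(apply(abs(M), 2, max), 1)
  for (it in seq_len(maxit)) {
    M_new <- .sweep_fe(M, w, cm, tindex, st)
    delta <- max(apply(abs(M_new - M), 2, max) / col_scale)
    M <- M_new
    if (delta < tol) return(list(M = M, iterations = it, converged = TRUE))
  }
  warning("within transformation did not fully converge (delta = ", delta, ")")
  list(M = M, iterations = maxit, converged = FALSE)
}

# identified-parameter count of the absorbed fixed-effect space:
# dim(county-month cells spanning (1, t)) + dim(state-year-month cells)
# minus the overlap, which is the span of (1, t) within state-month cells
.fe_rank <- function(dt) {
  cm_dim <- dt[, .(d = min(2L, uniqueN(month_index))),
               by = .(county_id, month)][, sum(d)]
  st_dim <- uniqueN(dt[, .(state_id, year, month)])
  overlap <- dt[, .(d = min(2L, uniqueN(month_index))),
                by = .(state_id, month)][, sum(d)]
  cm_dim + st_dim - overlap
}

#' Fit the mortality panel model
#'
#' Weighted within-estimation of the monthly mortality rate on the summed
#' 13-column basis and the above-median-rainfall indicator, absorbing
#' county-month intercepts, county-month linear trends, and
#' state-year-month effects, weighting by base-year county population, and
#' clustering standard errors at the WFO.  Point estimates match explicit
#' dummy-variable weighted least squares; the covariance is the one-way
#' cluster sandwich with small-sample factor G/(G-1) * (N-1)/(N-K), where
#' K counts the identified parameters including absorbed effects.
#'
#' @param design county-month design from [aggregate_monthly()] (columns
#'   `x1`..`x13`, `mortality_rate`, `rain_above_median`, `weight`,
#'   `month_index`, id keys).
#' @param cluster column name to cluster on (default `"wfo_id"`).
#' @param xcols names of the response-surface columns (default
#'   `x1`..`x13`); interaction-augmented designs pass the wider set.
#' @return object of class `panel_fit`: `beta` (and `se`), `vcov`,
#'   `rain_coef`, `n_obs`, `n_clusters`, `K`, `knots`, convergence info.
#' @export
fit_panel <- function(design, cluster = "wfo_id",
                      xcols = paste0("x", 1:13)) {
  dt <- as.data.table(design)
  stopifnot(all(c(xcols, "mortality_rate", "rain_above_median", "weight",
                  "month_index", "county_id", "state_id", "year", "month",
                  cluster) %in% names(dt)))
  dense_cols <- c(xcols, "rain_above_median")
  M <- cbind(as.matrix(dt[, ..dense_cols]), y = dt$mortality_rate)
  w <- dt$weight
  stopifnot(all(w > 0))
  cm <- paste(dt$county_id, dt$month)
  st <- paste(dt$state_id, dt$year, dt$month)
  dm <- .demean_fe(M, w, cm, dt$month_index, st)
  p <- length(dense_cols)
  Xt <- dm$M[, seq_len(p), drop = FALSE]
  yt <- dm$M[, p + 1L]
  fit <- lm.wfit(Xt, yt, w)
  if (anyNA(fit$coefficients)) {
    bad <- dense_cols[is.na(fit$coefficients)]
    stop("collinear design after fixed-effect absorption; offending ",
         "columns: ", paste(bad, collapse = ", "))
  }
  res <- fit$residuals
  cl <- dt[[cluster]]
  G <- uniqueN(cl)
  K <- p + .fe_rank(dt)
  n <- nrow(dt)
  bread <- chol2inv(chol(crossprod(Xt * sqrt(w))))
  scores <- rowsum(Xt * (w * res), cl)
  meat <- crossprod(scores)
  if (G < 2) {
    warning("single cluster: cluster-robust inference refused; ",
            "vcov set to NA")
    V <- matrix(NA_real_, p, p)
  } else {
    adj <- G / (G - 1) * (n - 1) / (n - K)
    V <- adj * bread %*% meat %*% bread
    V <- (V + t(V)) / 2
  }
  dimnames(V) <- list(dense_cols, dense_cols)
  beta <- fit$coefficients
  names(beta) <- dense_cols
  nb <- length(xcols)
  out <- list(beta = beta[seq_len(nb)],
              rain_coef = beta[["rain_above_median"]],
              coef_all = beta,
              vcov = V[seq_len(nb), seq_len(nb), drop = FALSE],
              vcov_all = V,
              se = sqrt(pmax(diag(V)[seq_len(nb)], 0)),
              n_obs = n, n_clusters = G, K = K,
              xcols = xcols,
              knots = attr(design, "knots"),
              demean_iterations = dm$iterations,
              converged = dm$converged)
  class(out) <- "panel_fit"
  out
}

#' Fit the heterogeneous-coefficients panel model
#'
#' Allows the 13-vector response to vary linearly with Winsorized county
#' characteristics: beta_c = beta_bar + mu_T,c * gamma_T + sigma_T,c *
#' gamma_sigma + RMSE_c * gamma_rmse (included dimensions selectable).
#' The design is augmented with one 13-column interaction block per
#' included characteristic; absorption, weights, and clustering are as in
#' [fit_panel()].
#'
#' @param design county-month design from [aggregate_monthly()].
#' @param characteristics from [compute_county_characteristics()], with
#'   characteristics already Winsorized (see [winsorize_weighted()]);
#'   attribute bands are carried into the fit for later clipping.
#' @param dims subset of `c("mu_T", "sigma_T", "rmse_c")`.
#' @return object of class `het_panel_fit` with `beta_bar`, a `gamma` list
#'   (one 13-vector per dim), the full clustered `vcov`, and the Winsorized
#'   bands per characteristic.
#' @export
fit_heterogeneous_panel <- function(design, characteristics,
                                    dims = c("mu_T", "sigma_T", "rmse_c")) {
  dims <- match.arg(dims, several.ok = TRUE)
  stopifnot(length(dims) >= 1)
  dt <- as.data.table(design)
  ch <- as.data.table(characteristics)
  missing_c <- setdiff(unique(dt$county_id), ch$county_id)
  if (length(missing_c) > 0)
    stop("characteristics missing for counties: ",
         paste(utils::head(missing_c, 5), collapse = ", "))
  bands <- lapply(dims, function(d) attr(ch[[d]], "band"))
  names(bands) <- dims
  dt <- merge(dt, ch[, c("county_id", dims), with = FALSE],
              by = "county_id")
  base_cols <- paste0("x", 1:13)
  xcols <- base_cols
  for (d in dims) {
    newc <- paste0(base_cols, "_", d)
    dt[, (newc) := lapply(.SD, function(x) x * dt[[d]]),
       .SDcols = base_cols]
    xcols <- c(xcols, newc)
  }
  setattr(dt, "knots", attr(design, "knots"))
  fit <- fit_panel(dt, xcols = xcols)
  gamma <- lapply(dims, function(d)
    unname(fit$beta[paste0(base_cols, "_", d)]))
  names(gamma) <- dims
  out <- list(beta_bar = unname(fit$beta[base_cols]),
              gamma = gamma, dims = dims, bands = bands,
              vcov = fit$vcov, se = fit$se,
              coef_all = fit$coef_all, vcov_all = fit$vcov_all,
              n_obs = fit$n_obs, n_clusters = fit$n_clusters,
              K = fit$K, xcols = fit$xcols, knots = fit$knots)
  class(out) <- c("het_panel_fit", "panel_fit")
  out
}

#' Joint Wald test that all heterogeneity slopes are zero
#'
#' Chi-squared Wald test with the clustered covariance.  A one-way cluster
#' covariance has rank at most G - 1, so when the number of restrictions
#' exceeds that the test uses the Moore-Penrose pseudoinverse with degrees
#' of freedom equal to the covariance rank.
#'
#' @param fit a `het_panel_fit`.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
wald_gamma_test <- function(fit) {
  stopifnot(inherits(fit, "het_panel_fit"))
  idx <- which(!fit$xcols %in% paste0("x", 1:13))
  theta <- fit$coef_all[fit$xcols][idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  # scale for numerical rank stability, then pseudo-invert
  s <- sqrt(pmax(diag(V), .Machine$double.xmin))
  Vs <- V / outer(s, s)
  ev <- eigen(Vs, symmetric = TRUE)
  pos <- ev$values > max(ev$values) * 1e-8
  r <- sum(pos)
  Vinv <- ev$vectors[, pos, drop = FALSE] %*%
    diag(1 / ev$values[pos], r) %*% t(ev$vectors[, pos, drop = FALSE])
  ts <- theta / s
  stat <- as.numeric(t(ts) %*% Vinv %*% ts)
  list(statistic = stat, df = r,
       p_value = stats::pchisq(stat, r, lower.tail = FALSE))
}

#' Effective county coefficient vector
#'
#' beta_c = beta_bar + sum over included dims of characteristic * gamma,
#' with out-of-band characteristics clipped to the Winsorized 5th-95th
#' band (with a warning), mirroring the restriction applied when
#' projecting with evolved characteristics.
#'
#' @param fit a `panel_fit` or `het_panel_fit`.
#' @param characteristics for heterogeneous fits, a list or one-row
#'   data.frame with the included characteristic values.
#' @return numeric 13-vector.
#' @export
county_beta <- function(fit, characteristics = NULL) {
  if (!inherits(fit, "het_panel_fit")) return(unname(fit$beta))
  if (is.null(characteristics))
    stop("characteristics required for a heterogeneous fit")
  b <- fit$beta_bar
  for (d in fit$dims) {
    v <- as.numeric(characteristics[[d]])
    band <- fit$bands[[d]]
    if (!is.null(band) && (v < band[1] || v > band[2])) {
      warning("characteristic ", d, " outside the Winsorized band; clipped")
      v <- min(max(v, band[1]), band[2])
    }
    b <- b + v * fit$gamma[[d]]
  }
  b
}

#' Evaluate the fitted response surface
#'
#' Returns x(T, e) . beta_c, the fitted daily mortality-rate contribution
#' (deaths per 100,000 per day) at temperature `temp` and demeaned forecast
#' error `e`.
#'
#' @param fit a `panel_fit` or `het_panel_fit`.
#' @param temp,e numeric vectors (recycled to common length).
#' @param characteristics per-county characteristics for heterogeneous
#'   fits (see [county_beta()]).
#' @return numeric vector of surface values.
#' @export
predict_surface <- function(fit, temp, e, characteristics = NULL) {
  n <- max(length(temp), length(e))
  temp <- rep_len(temp, n); e <- rep_len(e, n)
  b <- county_beta(fit, characteristics)
  X <- build_daily_basis(temp, e, basis_spec(knots = fit$knots))
  as.numeric(X %*% b)
}

#' Residualized air-conditioning association diagnostic
#'
#' Residualizes both the county-level hot-day excess mortality rate from
#' forecast errors and air conditioning take-up on the three county
#' characteristics (with intercept), trims counties with residualized AC
#' take-up outside the 2.5th-97.5th percentiles, drops the four lowest
#' mortality-residual counties (low-population cold outliers), and returns
#' the residual pairs with a lowess smooth.
#'
#' @param county_error_mortality named numeric vector (names = county ids)
#'   of hot-day excess mortality from forecast errors.
#' @param ac_takeup named numeric vector of AC take-up in \[0, 1\].
#' @param characteristics county characteristics table.
#' @param lowess_f lowess span (default 2/3); 3 robustness iterations.
#' @return list with `residuals` (data.table of pairs) and `lowess`.
#' @export
residualized_ac_association <- function(county_error_mortality, ac_takeup,
                                        characteristics, lowess_f = 2 / 3) {
  ch <- as.data.table(characteristics)
  dt <- ch[, .(county_id, mu_T, sigma_T, rmse_c)]
  dt[, em := county_error_mortality[county_id]]
  dt[, ac := ac_takeup[county_id]]
  dt <- dt[complete.cases(dt)]
  r_em <- residuals(lm(em ~ mu_T + sigma_T + rmse_c, data = dt))
  r_ac <- residuals(lm(ac ~ mu_T + sigma_T + rmse_c, data = dt))
  qb <- quantile(r_ac, c(0.025, 0.975))
  keep <- r_ac >= qb[1] & r_ac <= qb[2]
  drop4 <- rank(r_em, ties.method = "first") <= 4
  keep <- keep & !drop4
  if (sum(keep) < 10)
    stop("fewer than 10 counties remain after trimming")
  res <- data.table(county_id = dt$county_id[keep],
                    ac_resid = r_ac[keep], em_resid = r_em[keep])
  lw <- lowess(res$ac_resid, res$em_resid, f = lowess_f, iter = 3)
  list(residuals = res, lowess = lw)
}
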