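# Expert elicitation: percentile triplets of future forecast accuracy are
# calibrated to skew-lognormal distributions (exp of a skew-normal on the
# log scale), pooled into a mixture across experts, and converted into
# RMSE scenario targets and annual accuracy trajectories.

# ---- skew-normal primitives -------------------------------------------

#' Owen's T function
#'
#' T(h, a) = (1/2pi) Integral_0^a exp(-h^2 (1+x^2)/2) / (1+x^2) dx,
#' computed by adaptive quadrature.  Used for the skew-normal CDF.
#'
#' @param h,a scalars.
#' @return T(h, a).
#' @keywords internal
owen_t <- function(h, a) {
  if (a == 0) return(0)
  sgn <- sign(a); a <- abs(a)
  val <- integrate(function(x) exp(-0.5 * h^2 * (1 + x^2)) / (1 + x^2),
                   0, a, rel.tol = 1e-12, abs.tol = 1e-14)$value
  sgn * val / (2 * pi)
}

#' Standard skew-normal CDF
#'
#' CDF of the skew-normal with location 0, scale 1, shape `alpha`:
#' Phi(x) - 2 T(x, alpha).
#'
#' @param x quantile(s).
#' @param alpha shape parameter.
#' @return probabilities.
#' @export
psn_standard <- function(x, alpha) {
  vapply(x, function(xi) {
    p <- pnorm(xi) - 2 * owen_t(xi, alpha)
    min(max(p, 0), 1)
  }, numeric(1))
}

#' Standard skew-normal quantile
#'
#' Inverse of [psn_standard()], by root bracketing and `uniroot`.
#'
#' @param p probabilities in (0, 1).
#' @param alpha shape parameter.
#' @return quantiles.
#' @export
qsn_standard <- function(p, alpha) {
  stopifnot(all(p > 0 & p < 1))
  vapply(p, function(pi) {
    # skew-normal quantiles are bracketed by normal quantiles shifted by
    # the maximal mean shift |delta| sqrt(2/pi) < 1
    lo <- qnorm(pi) - 2; hi <- qnorm(pi) + 2
    while (psn_standard(lo, alpha) > pi) lo <- lo - 2
    while (psn_standard(hi, alpha) < pi) hi <- hi + 2
    uniroot(function(x) psn_standard(x, alpha) - pi, c(lo, hi),
            tol = 1e-12)$root
  }, numeric(1))
}

# ---- percentile calibration -------------------------------------------

#' Fit a skew-lognormal to a 1st/50th/99th percentile triplet
#'
#' Finds (xi, omega, alpha) such that exp(xi + omega * Z_alpha) has the
#' requested 1st, 50th, and 99th percentiles, where Z_alpha is standard
#' skew-normal.  On the log scale the three equations reduce to a
#' one-dimensional root in alpha via the quantile-spacing ratio
#' (log p99 - log p50) / (log p50 - log p01), after which omega and xi are
#' closed-form.  Triplets whose asymmetry exceeds what the skew-normal can
#' express are fitted at the boundary shape and flagged.
#'
#' @param p01,p50,p99 strictly positive, nondecreasing accuracy values
#'   (smaller is better; p01 = best case).
#' @param alpha_max search bound for |alpha|.
#' @return a list of class `skew_lognormal` with `xi`, `omega`, `alpha`,
#'   `residual` (max relative error of the refitted percentiles on the log
#'   scale), and `boundary` flag.
#' @export
fit_skew_lognormal <- function(p01, p50, p99, alpha_max = 50) {
  if (!(p01 > 0 && p01 <= p50 && p50 <= p99))
    stop("need 0 < p01 <= p50 <= p99")
  if (p01 == p99) stop("degenerate triplet (all percentiles equal)")
  l <- log(c(p01, p50, p99))
  target_ratio <- (l[3] - l[2]) / (l[2] - l[1])
  ratio <- function(alpha) {
    z <- qsn_standard(c(0.01, 0.5, 0.99), alpha)
    (z[3] - z[2]) / (z[2] - z[1])
  }
  boundary <- FALSE
  if (!is.finite(target_ratio) || target_ratio <= 0) {
    # one spacing is zero: maximal asymmetry, clamp at the bound
    alpha <- if (identical(l[2], l[1])) alpha_max else -alpha_max
    boundary <- TRUE
  } else {
    f <- function(a) ratio(a) - target_ratio
    f_lo <- f(-alpha_max); f_hi <- f(alpha_max)
    if (f_lo * f_hi > 0) {
      alpha <- if (abs(f_lo) < abs(f_hi)) -alpha_max else alpha_max
      boundary <- TRUE
    } else {
      alpha <- uniroot(f, c(-alpha_max, alpha_max), tol = 1e-10)$root
    }
  }
  z <- qsn_standard(c(0.01, 0.5, 0.99), alpha)
  omega <- (l[3] - l[1]) / (z[3] - z[1])
  xi <- l[2] - omega * z[2]
  refit <- xi + omega * z
  residual <- max(abs(refit - l) / pmax(abs(l), 1))
  out <- list(xi = xi, omega = omega, alpha = alpha,
              residual = residual, boundary = boundary)
  class(out) <- "skew_lognormal"
  out
}

#' Skew-lognormal quantile function
#' @param p probabilities in (0, 1).
#' @param fit a [fit_skew_lognormal()] object.
#' @return quantiles (strictly positive).
#' @export
qslnorm <- function(p, fit) exp(fit$xi + fit$omega * qsn_standard(p, fit$alpha))

#' Skew-lognormal CDF
#' @param q positive quantiles.
#' @param fit a [fit_skew_lognormal()] object.
#' @return probabilities.
#' @export
pslnorm <- function(q, fit) {
  out <- numeric(length(q))
  pos <- q > 0
  out[pos] <- psn_standard((log(q[pos]) - fit$xi) / fit$omega, fit$alpha)
  out
}

# ---- unit handling -----------------------------------------------------

#' Convert expert responses to RMSE units
#'
#' MSE responses are mapped by square root; MAE responses via an ordinary
#' least-squares line RMSE = a + b * MAE fitted to historical (MAE, RMSE)
#' pairs (observed at the forecast-office-year level, where the relation is
#' strongly linear).
#'
#' @param responses expert response table (from
#'   [simulate_expert_responses()] or a CSV with the same columns).
#' @param historical_pairs `data.frame` with columns `mae` and `rmse`.
#' @return the responses with all accuracy columns in RMSE units and
#'   `metric` set to `"RMSE"`; the fitted line is in attribute
#'   `"mae_rmse_fit"`.
#' @export
convert_mae_to_rmse <- function(responses, historical_pairs) {
  stopifnot(nrow(historical_pairs) >= 2)
  if (var(historical_pairs$mae) == 0)
    stop("degenerate (MAE, RMSE) pairs: zero MAE variance")
  fit <- lm(rmse ~ mae, data = historical_pairs)
  ab <- coef(fit)
  res <- as.data.table(copy(responses))
  acc_cols <- c("acc_2005", "acc_2020", "p01", "p50", "p99")
  res[metric == "MSE", (acc_cols) := lapply(.SD, sqrt), .SDcols = acc_cols]
  res[metric == "MSE", metric := "RMSE"]
  res[metric == "MAE", (acc_cols) := lapply(.SD, function(x) ab[1] + ab[2] * x),
      .SDcols = acc_cols]
  res[metric == "MAE", metric := "RMSE"]
  setattr(res, "mae_rmse_fit", ab)
  res[]
}

#' Normalize accuracy responses to multiplicative changes
#'
#' Divides each horizon's percentile triplet by the expert's reported 2020
#' accuracy, giving the distribution of the 2020-to-horizon multiplicative
#' RMSE change (change < 1 = improvement; > 1 = degradation).  Experts
#' without a positive 2020 anchor are excluded (listed in attribute
#' `"excluded"`).
#'
#' @param responses response table in RMSE units.
#' @return table with columns `expert`, `horizon`, `chg01`, `chg50`,
#'   `chg99`, `chg_2005_2020` (observed-period change, for performance
#'   weighting), and a `degenerate` flag for point-mass triplets.
#' @export
normalize_changes <- function(responses) {
  res <- as.data.table(responses)
  bad <- res[is.na(acc_2020) | acc_2020 <= 0]
  res <- res[!is.na(acc_2020) & acc_2020 > 0]
  out <- res[, .(expert, horizon,
                 chg01 = p01 / acc_2020,
                 chg50 = p50 / acc_2020,
                 chg99 = p99 / acc_2020,
                 chg_2005_2020 = acc_2020 / acc_2005,
                 degenerate = p01 == p99)]
  setattr(out, "excluded", unique(bad$expert))
  out[]
}

# ---- mixture and weights ----------------------------------------------

#' Mixture of skew-lognormal components
#'
#' @param fits list of [fit_skew_lognormal()] objects.
#' @param weights nonnegative weights (normalized to sum 1); equal by
#'   default, reflecting no prior information favouring specific experts.
#' @return object of class `sln_mixture` with `pmix(q)` CDF and `qmix(p)`
#'   quantile (monotone bisection on the mixture CDF).
#' @export
build_mixture <- function(fits, weights = NULL) {
  stopifnot(length(fits) >= 1)
  w <- weights %||% rep(1 / length(fits), length(fits))
  stopifnot(length(w) == length(fits), all(w >= 0), sum(w) > 0)
  w <- w / sum(w)
  obj <- list(components = fits, weights = w)
  class(obj) <- "sln_mixture"
  obj
}

#' Mixture CDF
#' @param obj an `sln_mixture`.
#' @param q positive quantiles.
#' @return probabilities (weighted sum of component CDFs).
#' @export
pmix <- function(obj, q) {
  out <- numeric(length(q))
  for (i in seq_along(obj$components))
    out <- out + obj$weights[i] * pslnorm(q, obj$components[[i]])
  out
}

#' Mixture quantile
#' @param obj an `sln_mixture`.
#' @param p probabilities in (0, 1).
#' @return quantiles by root finding on the mixture CDF.
#' @export
qmix <- function(obj, p) {
  stopifnot(all(p > 0 & p < 1))
  rng <- range(unlist(lapply(obj$components, function(f)
    qslnorm(c(1e-6, 1 - 1e-6), f))))
  vapply(p, function(pi)
    uniroot(function(q) pmix(obj, q) - pi, rng, tol = 1e-10,
            extendInt = "upX")$root, numeric(1))
}

#' Exponential performance weights
#'
#' w_i proportional to exp(-lam * (y_i - y_obs)^2), normalized to sum 1:
#' experts whose reported 2005-2020 accuracy change is closest to the
#' observed change are up-weighted.
#'
#' @param reported_changes numeric vector y_i.
#' @param observed_change scalar y_obs.
#' @param lam nonnegative sharpness (default 20).
#' @return weights summing to 1.
#' @export
performance_weights <- function(reported_changes, observed_change, lam = 20) {
  stopifnot(lam >= 0)
  w <- exp(-lam * (reported_changes - observed_change)^2)
  w / sum(w)
}

# ---- scenarios ---------------------------------------------------------

#' Scenario RMSE targets from the elicited mixture
#'
#' Scales the 2020 base RMSE by mixture quantiles of the multiplicative
#' change: accelerated = 10th percentile (most improvement), central =
#' median, slowed = 90th percentile.
#'
#' @param mixture an `sln_mixture` for the 2100 change.
#' @param base_rmse_2020 observed nationwide RMSE in 2020 (deg C).
#' @param percentiles percent levels, default `c(10, 50, 90)`.
#' @return `data.table` with `name`, `percentile`, `target_change_2100`,
#'   `rmse_2100`.
#' @export
scenario_targets <- function(mixture, base_rmse_2020,
                             percentiles = c(10, 50, 90)) {
  stopifnot(base_rmse_2020 > 0)
  chg <- qmix(mixture, percentiles / 100)
  data.table(name = c("accelerated", "central", "slowed")[seq_along(percentiles)],
             percentile = percentiles,
             target_change_2100 = chg,
             rmse_2100 = base_rmse_2020 * chg)
}

#' Extrapolate an annual accuracy trajectory through a 2100 target
#'
#' Fits a constant annual percentage change to the historical RMSE series
#' (least squares on log first differences, which keeps extrapolations
#' positive), then rescales the rate so the trajectory from the last
#' historical year passes exactly through `target_2100`.
#'
#' @param historical_rmse named numeric vector, names = years, values =
#'   RMSE (deg C).
#' @param target_2100 target RMSE in 2100 (> 0).
#' @param end_year trajectory end (default 2100).
#' @return list with `r_hat` (fitted historical annual rate), `r_star`
#'   (scenario rate), and `trajectory` (named vector year -> RMSE from the
#'   last historical year to `end_year`).
#' @export
extrapolate_accuracy_path <- function(historical_rmse, target_2100,
                                      end_year = 2100) {
  stopifnot(length(historical_rmse) >= 3, target_2100 > 0)
  yrs <- as.integer(names(historical_rmse))
  o <- order(yrs); yrs <- yrs[o]; v <- as.numeric(historical_rmse[o])
  stopifnot(all(v > 0))
  dl <- diff(log(v)) / diff(yrs)
  r_hat <- exp(mean(dl)) - 1
  y_last <- yrs[length(yrs)]; v_last <- v[length(v)]
  r_star <- (target_2100 / v_last)^(1 / (end_year - y_last)) - 1
  traj_years <- y_last:end_year
  traj <- v_last * (1 + r_star)^(traj_years - y_last)
  names(traj) <- traj_years
  list(r_hat = r_hat, r_star = r_star, trajectory = traj)
}
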