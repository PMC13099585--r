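# The daily design couples a 4th-order polynomial in realized temperature
# with a 3-column natural cubic spline in the demeaned day-ahead forecast
# error, plus quadratic-in-temperature interactions: 4 + 3 + 6 = 13 columns.

#' Default basis specification
#'
#' Fourth-order temperature polynomial; error spline with internal knots at
#' the 35th/65th and boundary knots at the 5th/95th percentiles of the
#' population-weighted demeaned forecast-error distribution; interactions of
#' each spline column with T and T^2.
#'
#' @param knots optional numeric vector of 4 increasing knots (boundary,
#'   internal, internal, boundary).  When supplied, percentile targets are
#'   ignored and `resolve_knots()` passes them through.
#' @return a list of class `basis_spec`.
#' @export
basis_spec <- function(knots = NULL) {
  spec <- list(poly_degree = 4L,
               internal_pct = c(35, 65),
               boundary_pct = c(5, 95),
               interaction_degree = 2L,
               knots = knots)
  if (!is.null(knots)) {
    stopifnot(length(knots) == 4L, !is.unsorted(knots, strictly = TRUE))
  }
  class(spec) <- "basis_spec"
  spec
}

#' Demean forecast errors within groups
#'
#' Subtracts group means from the raw forecast error to remove persistent
#' offsets between the forecast and observation products.  The default
#' (county) removes a county-specific bias; alternatives are county-month,
#' county-month-temperature-bin (5 degree C bins), or none.
#'
#' @param records county-day `data.table` with columns `county_id`, `date`,
#'   `temp`, `error`.
#' @param level one of `"county"`, `"county-month"`,
#'   `"county-month-tempbin"`, `"none"`.
#' @return the records with an `error_demeaned` column; the level used is
#'   recorded in attribute `"demean_level"`.
#' @export
demean_errors <- function(records,
                          level = c("county", "county-month",
                                    "county-month-tempbin", "none")) {
  level <- match.arg(level)
  stopifnot(is.data.table(records), "error" %in% names(records))
  rec <- copy(records)
  if (level == "none") {
    rec[, error_demeaned := error]
  } else {
    rec[, .grp_month := month(date)]
    rec[, .grp_bin := 5 * floor(temp / 5)]
    gcols <- switch(level,
      "county"               = "county_id",
      "county-month"         = c("county_id", ".grp_month"),
      "county-month-tempbin" = c("county_id", ".grp_month", ".grp_bin"))
    rec[, error_demeaned := error - mean(error), by = gcols]
    rec[, c(".grp_month", ".grp_bin") := NULL]
  }
  setattr(rec, "demean_level", level)
  rec
}

#' Resolve percentile knot targets to numeric knots
#'
#' Replaces the percentile targets in a [basis_spec()] by weighted empirical
#' quantiles of the demeaned forecast-error distribution; explicit numeric
#' knots pass through unchanged.
#'
#' @param records county-day records with `error_demeaned`.
#' @param spec a [basis_spec()].
#' @param weights per-record weights (e.g. county population replicated
#'   across days); defaults to equal weights.
#' @return the spec with `$knots` set to 4 increasing numeric values.
#' @export
resolve_knots <- function(records, spec = basis_spec(), weights = NULL) {
  if (!is.null(spec$knots)) return(spec)
  stopifnot("error_demeaned" %in% names(records))
  e <- records$error_demeaned
  w <- weights %||% rep(1, length(e))
  pr <- sort(c(spec$boundary_pct, spec$internal_pct)) / 100
  kn <- weighted_quantile(e, w, pr)
  if (length(unique(kn)) < 4L)
    stop("fewer distinct error values than knots")
  spec$knots <- kn
  spec
}

#' Natural cubic spline basis (truncated-power form, no intercept)
#'
#' Three basis functions for 4 increasing knots (k1 < k2 < k3 < k4, the
#' outer two being boundary knots): N1(e) = e and, with
#' d_j(e) = \[(e - k_j)^3_+ - (e - k_4)^3_+\] / (k_4 - k_j),
#' N_(m+1)(e) = d_m(e) - d_3(e) for m = 1, 2.  Each function is exactly
#' linear outside the boundary knots (zero second derivative), so effects
#' beyond the observed error support extrapolate linearly.
#'
#' @param e numeric vector of (demeaned) forecast errors.
#' @param knots 4 strictly increasing knots.
#' @return an `length(e) x 3` matrix.
#' @export
spline_basis <- function(e, knots) {
  stopifnot(length(knots) == 4L)
  if (is.unsorted(knots, strictly = TRUE)) stop("knots must be increasing")
  dj <- function(j) {
    (pmax(e - knots[j], 0)^3 - pmax(e - knots[4], 0)^3) /
      (knots[4] - knots[j])
  }
  d3 <- dj(3)
  cbind(N1 = e, N2 = dj(1) - d3, N3 = dj(2) - d3)
}

#' Build the 13-column daily basis
#'
#' Column order: x1..x4 = T, T^2, T^3, T^4; x5..x7 = N1(e), N2(e), N3(e);
#' x8..x10 = Nj(e) * T; x11..x13 = Nj(e) * T^2.
#'
#' @param temp realized daily-mean temperature (deg C).
#' @param e_demeaned demeaned forecast error (deg C).
#' @param spec a [basis_spec()] with numeric knots resolved.
#' @return an `n x 13` matrix with columns `x1`..`x13`.
#' @export
build_daily_basis <- function(temp, e_demeaned, spec) {
  if (is.null(spec$knots)) stop("knots not resolved; call resolve_knots()")
  if (any(!is.finite(temp)) || any(!is.finite(e_demeaned)))
    stop("non-finite temperature or error input")
  stopifnot(length(temp) == length(e_demeaned))
  N <- spline_basis(e_demeaned, spec$knots)
  X <- cbind(temp, temp^2, temp^3, temp^4,
             N, N * temp, N * temp^2)
  colnames(X) <- paste0("x", 1:13)
  X
}

#' Aggregate the daily basis to county-month design rows
#'
#' Sums the 13 daily basis columns over days within each county-month, joins
#' the county-month mortality rates, attaches the above-median-rainfall
#' indicator (monthly precipitation total versus the county's own sample
#' median), base-year population weights, and the fixed-effect keys.  Months
#' with mortality but no weather rows are excluded and reported in the
#' `"exceptions"` attribute.
#'
#' @param records county-day records with `temp`, `error_demeaned`,
#'   `precip`, `date`.
#' @param mortality county-month `data.table` with `county_id`, `year`,
#'   `month`, `mortality_rate`.
#' @param counties county profile table (for `population_base`, `state_id`,
#'   `wfo_id`).
#' @param spec resolved [basis_spec()].
#' @return a county-month `data.table` with columns `x1`..`x13`,
#'   `mortality_rate`, `rain_above_median`, `weight`, `month_index`, and the
#'   id keys; knots stored in attribute `"knots"`.
#' @export
aggregate_monthly <- function(records, mortality, counties, spec) {
  stopifnot(!is.null(spec$knots))
  X <- build_daily_basis(records$temp, records$error_demeaned, spec)
  dt <- data.table(county_id = records$county_id,
                   year = year(records$date),
                   month = month(records$date),
                   precip = records$precip)
  dt <- cbind(dt, as.data.table(X))
  agg <- dt[, c(lapply(.SD, sum), .N),
            by = .(county_id, year, month),
            .SDcols = c(paste0("x", 1:13), "precip")]
  setnames(agg, "N", "n_days")
  agg[, rain_above_median := as.numeric(precip > stats::median(precip)),
      by = county_id]
  mo <- as.data.table(mortality)[, .(county_id, year, month, mortality_rate)]
  des <- merge(agg, mo, by = c("county_id", "year", "month"))
  missing_weather <- mo[!agg, on = c("county_id", "year", "month")]
  des <- merge(des,
               counties[, .(county_id, state_id, wfo_id,
                            weight = population_base)],
               by = "county_id")
  ym0 <- min(des$year * 12L + des$month)
  des[, month_index := year * 12L + month - ym0]
  setkey(des, county_id, year, month)
  setattr(des, "knots", spec$knots)
  setattr(des, "exceptions", missing_weather)
  des[]
}
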