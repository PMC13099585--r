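#' @import data.table
#' @importFrom stats lm lm.wfit glm glm.fit coef vcov predict quantile sd
#'   var rnorm runif rbinom rgamma pnorm qnorm dnorm integrate uniroot
#'   optimize weighted.mean complete.cases pchisq qt lowess setNames
#'   residuals fitted as.formula model.matrix
#' @importFrom utils head
NULL

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' generators are deterministic in their `seed` argument without disturbing
#' the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Weighted empirical quantile
#'
#' Quantile of `x` with nonnegative weights `w`, by linear interpolation on
#' the midpoint cumulative-weight grid p_i = (cumw_i - w_i/2) / sum(w).
#' Values outside the grid clamp to the extreme order statistics.
#'
#' @param x numeric values.
#' @param w nonnegative weights, same length as `x`.
#' @param probs probabilities in \[0, 1\].
#' @return numeric vector of quantiles, one per element of `probs`.
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0), any(w > 0),
            all(probs >= 0 & probs <= 1))
  keep <- w > 0 & is.finite(x)
  if (!any(keep)) stop("no finite values with positive weight")
  x <- x[keep]; w <- w[keep]
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  p <- (cw - w / 2) / cw[length(cw)]
  vapply(probs, function(pr) {
    if (pr <= p[1]) return(x[1])
    if (pr >= p[length(p)]) return(x[length(x)])
    stats::approx(p, x, xout = pr, ties = "ordered")$y
  }, numeric(1))
}

#' Winsorize values at weighted percentiles
#'
#' Clips values below the weighted `p_lo` percentile and above the weighted
#' `p_hi` percentile to those percentiles, leaving interior order statistics
#' untouched.  Used for the county characteristics entering the
#' heterogeneous response model.
#'
#' @param values numeric vector.
#' @param weights nonnegative weights (e.g. base-year population).
#' @param p_lo,p_hi percentile bounds in percent (defaults 5 and 95).
#' @return numeric vector of clipped values with attribute `"band"` holding
#'   the two clip points.
#' @export
winsorize_weighted <- function(values, weights, p_lo = 5, p_hi = 95) {
  if (length(values) == 0L) stop("empty input")
  stopifnot(length(values) == length(weights), p_lo < p_hi)
  band <- weighted_quantile(values, weights, c(p_lo, p_hi) / 100)
  out <- pmin(pmax(values, band[1]), band[2])
  attr(out, "band") <- band
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
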