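# Calibration of the log10-normal TSH model from printed summaries.
#
# TSH in reference populations is right-skewed and is analyzed on the
# log10 scale; the generator therefore draws log10(TSH) from a normal
# distribution whose parameters are recovered from published quartiles or
# central-95% bounds by quantile inversion.

#' Calibrate a log10-normal from median and quartiles
#'
#' Inverts the standard-normal quantile relationship: on the log10 scale,
#' `sigma = (log10 q75 - log10 q25) / (2 * qnorm(0.75))` (`qnorm(0.75)` =
#' 0.674489...), and `mu` is `log10(median)` when a median is supplied
#' (median takes precedence) or the midpoint of the log-quartiles
#' otherwise.
#'
#' @param median raw-scale median (mU/L), or `NULL` to use the quartile
#'   midpoint.
#' @param q25,q75 raw-scale quartiles (mU/L).
#' @return named numeric: `tsh_log10_mu`, `tsh_log10_sigma`.
#' @examples
#' calibrate_lognormal(median = 1.7, q25 = 1.7, q75 = 2.8)
#' @export
calibrate_lognormal <- function(median = NULL, q25, q75) {
  if (q25 <= 0 || q75 <= 0 || (!is.null(median) && median <= 0))
    stop("inputs must be strictly positive")
  if (q25 > q75) stop("q25 must not exceed q75")
  if (!is.null(median) && (median < q25 || median > q75))
    stop("median must lie between q25 and q75")
  mu <- if (is.null(median)) (log10(q25) + log10(q75)) / 2 else log10(median)
  sigma <- (log10(q75) - log10(q25)) / (2 * stats::qnorm(0.75))
  c(tsh_log10_mu = mu, tsh_log10_sigma = sigma)
}

#' Calibrate a log10-normal from central-95% bounds
#'
#' Chooses `mu`, `sigma` so the implied distribution's 2.5th and 97.5th
#' percentiles equal the given bounds exactly:
#' `mu = (log10 p2_5 + log10 p97_5)/2`,
#' `sigma = (log10 p97_5 - log10 p2_5) / (2 * qnorm(0.975))`.
#'
#' @param p2_5,p97_5 raw-scale bounds (mU/L), strictly ordered.
#' @return named numeric: `tsh_log10_mu`, `tsh_log10_sigma`.
#' @examples
#' calibrate_lognormal_from_bounds(0.4, 5.8)
#' @export
calibrate_lognormal_from_bounds <- function(p2_5, p97_5) {
  if (p2_5 <= 0 || p97_5 <= 0) stop("bounds must be strictly positive")
  if (p2_5 >= p97_5) stop("bounds must be strictly ordered (p2_5 < p97_5)")
  c(tsh_log10_mu = (log10(p2_5) + log10(p97_5)) / 2,
    tsh_log10_sigma = (log10(p97_5) - log10(p2_5)) / (2 * stats::qnorm(0.975)))
}

#' Analytic quantile of a calibrated log10-normal
#'
#' @param p probability.
#' @param params output of one of the calibrators.
#' @return raw-scale quantile (mU/L).
#' @export
lognormal_quantile <- function(p, params) {
  10^(params[["tsh_log10_mu"]] + params[["tsh_log10_sigma"]] * stats::qnorm(p))
}
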