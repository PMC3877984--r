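# Nonparametric reference-interval estimation.
#
# The reference interval is the central coverage fraction (default 95%,
# i.e. the 2.5th and 97.5th percentiles) of the screened, outlier-scanned
# series. Percentiles use the rank = p(n+1) convention with linear
# interpolation between order statistics, clamped to [1, n] - the CLSI
# nonparametric convention, identical to stats::quantile type 6.

#' Nonparametric percentile reference interval
#'
#' The caller is responsible for outlier scanning first (see
#' [dixon_outliers()]); this function only estimates percentiles.
#' Guideline practice asks for at least 120 reference subjects for
#' nonparametric 95% limits; smaller series (but never below 20) produce
#' a warning, not an error.
#'
#' @param x numeric vector of analyte values (analysis already on the
#'   desired scale), n >= 20.
#' @param coverage central proportion covered, in (0, 1); default 0.95.
#' @param rounding decimals for the reported bounds (default 1, the
#'   precision at which hormone RIs are printed).
#' @param analyte,unit optional provenance tags carried into the result.
#' @return object of class `reference_interval`: list with reported
#'   `lower`/`upper` (rounded), `lower_raw`/`upper_raw` (unrounded),
#'   `coverage`, `method = "nonparametric_rank"`, `n_used`, `rounding`,
#'   `analyte`, `unit`.
#' @examples
#' nonparametric_ri(1:119)  # ranks 3 and 117 -> (3, 117)
#' @export
nonparametric_ri <- function(x, coverage = 0.95, rounding = 1L,
                             analyte = NULL, unit = NULL) {
  x <- as.numeric(x[!is.na(x)])
  n <- length(x)
  if (n < 20L) stop("need at least 20 observations for a nonparametric RI")
  if (!is.numeric(coverage) || coverage <= 0 || coverage >= 1)
    stop("coverage must be in (0, 1)")
  if (n < 120L)
    warning("n = ", n, " < 120: nonparametric limits below the guideline minimum")
  p <- c((1 - coverage) / 2, 1 - (1 - coverage) / 2)
  b <- stats::quantile(x, p, type = 6, names = FALSE)
  out <- list(analyte = analyte, unit = unit,
              lower = round(b[1], rounding), upper = round(b[2], rounding),
              lower_raw = b[1], upper_raw = b[2],
              coverage = coverage, method = "nonparametric_rank",
              n_used = n, rounding = as.integer(rounding))
  class(out) <- "reference_interval"
  out
}

#' @export
print.reference_interval <- function(x, ...) {
  tag <- if (!is.null(x$analyte)) paste0(x$analyte, " ") else ""
  un <- if (!is.null(x$unit)) paste0(" ", x$unit) else ""
  cat(sprintf("%sreference interval (central %g%%, %s, n = %d): %s - %s%s\n",
              tag, 100 * x$coverage, x$method, x$n_used,
              format(x$lower), format(x$upper), un))
  invisible(x)
}

#' @export
format.reference_interval <- function(x, ...) {
  sprintf("%.*f - %.*f", x$rounding, x$lower, x$rounding, x$upper)
}
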