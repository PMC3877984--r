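# Analyte series: a numeric measurement vector tagged with its analyte,
# unit and scale (raw or log10). Most estimation functions accept a bare
# numeric vector; the tagged form documents which scale an analysis ran on.

#' Construct an analyte series
#'
#' @param values numeric vector of measurements, strictly positive when
#'   `scale = "raw"`.
#' @param analyte `"TSH"` or `"FT4"`.
#' @param unit measurement unit; defaults to the analyte's conventional
#'   unit (mU/L for TSH, ng/dL for FT4).
#' @param scale `"raw"` or `"log10"`.
#' @return object of class `analyte_series` (a numeric vector with
#'   attributes).
#' @export
analyte_series <- function(values, analyte = c("TSH", "FT4"), unit = NULL,
                           scale = c("raw", "log10")) {
  analyte <- match.arg(analyte)
  scale <- match.arg(scale)
  values <- as.numeric(values)
  if (scale == "raw" && any(!is.na(values) & values <= 0))
    stop("raw-scale values must be strictly positive")
  if (is.null(unit)) unit <- if (analyte == "TSH") "mU/L" else "ng/dL"
  structure(values, analyte = analyte, unit = unit, scale = scale,
            class = "analyte_series")
}

#' @export
print.analyte_series <- function(x, ...) {
  cat(sprintf("<analyte_series> %s [%s], scale = %s, n = %d\n",
              attr(x, "analyte"), attr(x, "unit"), attr(x, "scale"), length(x)))
  print(as.numeric(x), ...)
  invisible(x)
}

#' Log10-transform an analyte series
#'
#' Order-preserving and invertible; the analysis scale for TSH.
#'
#' @param series an [analyte_series()] on the raw scale, or a bare
#'   positive numeric vector.
#' @return the series on the log10 scale (same class as the input).
#' @export
log10_transform <- function(series) {
  v <- as.numeric(series)
  bad <- which(!is.na(v) & v <= 0)
  if (length(bad))
    stop("non-positive value at index ", paste(bad, collapse = ", "),
         ": cannot log10-transform")
  if (inherits(series, "analyte_series")) {
    if (attr(series, "scale") != "raw") stop("series is already on the log10 scale")
    structure(log10(v), analyte = attr(series, "analyte"),
              unit = paste0("log10(", attr(series, "unit"), ")"),
              scale = "log10", class = "analyte_series")
  } else log10(v)
}

#' Invert a log10 transform
#'
#' @param series log10-scale series or numeric vector.
#' @return raw-scale values.
#' @export
inv_log10_transform <- function(series) {
  v <- 10^as.numeric(series)
  if (inherits(series, "analyte_series")) {
    if (attr(series, "scale") != "log10") stop("series is not on the log10 scale")
    analyte_series(v, attr(series, "analyte"), scale = "raw")
  } else v
}

#' Descriptive summary of an analyte series
#'
#' Median, quartiles (rank = p(n+1) interpolation, the same convention as
#' [nonparametric_ri()]), range, mean, SD and a 95% confidence interval
#' for the median by the binomial order-statistic method.
#'
#' @param x numeric vector, n >= 2.
#' @param conf confidence level for the median CI.
#' @return named list.
#' @export
describe_series <- function(x, conf = 0.95) {
  x <- as.numeric(x[!is.na(x)])
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 6, names = FALSE)
  list(n = n, mean = mean(x), sd = stats::sd(x),
       median = q[2], q25 = q[1], q75 = q[3],
       min = min(x), max = max(x),
       median_ci = .median_ci(x, conf))
}

# Conservative binomial order-statistic CI for the median: the widest
# (x_(l), x_(u)) with l the largest rank whose lower tail does not exceed
# (1-conf)/2, u = n + 1 - l.
.median_ci <- function(x, conf = 0.95) {
  n <- length(x)
  xs <- sort(x)
  a <- (1 - conf) / 2
  l <- stats::qbinom(a, n, 0.5)
  while (l > 0 && stats::pbinom(l - 1, n, 0.5) > a) l <- l - 1
  if (l < 1L) return(c(lower = xs[1], upper = xs[n]))  # too few obs for the level
  c(lower = xs[l], upper = xs[n + 1 - l])
}
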