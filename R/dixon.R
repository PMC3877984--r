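# Dixon-type outlier screening before reference-interval estimation.
#
# Default is the CLSI-style range rule: an extreme observation is an
# outlier when its gap D to the nearest remaining neighbour exceeds one
# third of the whole range R; the rule is re-applied to either tail until
# nothing is flagged. The classical Dixon-Q ratio test (alpha = 0.05
# two-tailed critical values, n <= 30) is available for small series.

# Dixon-Q two-tailed critical values at alpha = 0.05 (Rorabacher's table):
# r10 for n = 3..7, r11 for 8..10, r21 for 11..13, r22 for 14..30.
.dixon_q_crit <- c(
  `3` = 0.970, `4` = 0.829, `5` = 0.710, `6` = 0.625, `7` = 0.568,
  `8` = 0.615, `9` = 0.570, `10` = 0.534,
  `11` = 0.625, `12` = 0.592, `13` = 0.565,
  `14` = 0.590, `15` = 0.568, `16` = 0.548, `17` = 0.531, `18` = 0.516,
  `19` = 0.503, `20` = 0.489, `21` = 0.478, `22` = 0.468, `23` = 0.457,
  `24` = 0.448, `25` = 0.440, `26` = 0.432, `27` = 0.426, `28` = 0.419,
  `29` = 0.413, `30` = 0.407)

# Dixon ratio for the min (tail = 1) or max (tail = 2) of sorted y.
.dixon_q_ratio <- function(y, tail) {
  n <- length(y)
  j <- if (n <= 7) 1L else if (n <= 10) 1L else if (n <= 13) 2L else 2L  # numerator skip
  k <- if (n <= 7) 0L else if (n <= 10) 1L else if (n <= 13) 1L else 2L  # denominator trim
  if (tail == 1L) {
    num <- y[1 + j] - y[1]; den <- y[n - k] - y[1]
  } else {
    num <- y[n] - y[n - j]; den <- y[n] - y[1 + k]
  }
  if (den == 0) 0 else num / den
}

#' Dixon outlier scan
#'
#' @param x numeric vector, n >= 3.
#' @param method `"clsi_one_third"` (default; D/R > 1/3 rule, robust at
#'   the series sizes typical of RI studies) or `"dixon_q"` (classical
#'   ratio test, n <= 30, alpha fixed at 0.05 by the embedded table).
#' @param alpha significance level; only 0.05 is supported for
#'   `"dixon_q"`.
#' @return object of class `dixon_report`: list with `flagged_indices`
#'   (positions in `x`, in removal order), `statistic_per_flag` (the D/R
#'   or Dixon ratio of each removed value), `method`, `n`, and `kept`
#'   (logical mask over `x`).
#' @examples
#' dixon_outliers(c(1, 2, 3, 4, 5, 100))
#' @export
dixon_outliers <- function(x, method = c("clsi_one_third", "dixon_q"),
                           alpha = 0.05) {
  method <- match.arg(method)
  x <- as.numeric(x)
  if (anyNA(x)) stop("missing values not allowed in an outlier scan")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (method == "dixon_q") {
    if (alpha != 0.05) stop("dixon_q critical values are tabulated for alpha = 0.05 only")
    if (n > 30L) stop("dixon_q is tabulated for n <= 30; use method = 'clsi_one_third'")
  }
  keep <- rep(TRUE, n)
  flagged <- integer()
  stats_f <- numeric()
  ord <- order(x)
  active <- ord  # indices into x, sorted by value
  repeat {
    m <- length(active)
    if (m < 3L) break
    y <- x[active]
    if (method == "clsi_one_third") {
      r <- y[m] - y[1]
      if (r == 0) break
      hi <- (y[m] - y[m - 1]) / r
      lo <- (y[2] - y[1]) / r
      if (hi >= lo && hi > 1 / 3) { drop <- m; stat <- hi }
      else if (lo > 1 / 3) { drop <- 1L; stat <- lo }
      else break
    } else {
      crit <- .dixon_q_crit[[as.character(m)]]
      hi <- .dixon_q_ratio(y, 2L)
      lo <- .dixon_q_ratio(y, 1L)
      if (hi >= lo && hi > crit) { drop <- m; stat <- hi }
      else if (lo > crit) { drop <- 1L; stat <- lo }
      else break
    }
    flagged <- c(flagged, active[drop])
    stats_f <- c(stats_f, stat)
    keep[active[drop]] <- FALSE
    active <- active[-drop]
  }
  out <- list(flagged_indices = flagged, statistic_per_flag = stats_f,
              method = method, n = n, kept = keep)
  class(out) <- "dixon_report"
  out
}

#' @export
print.dixon_report <- function(x, ...) {
  cat(sprintf("Dixon outlier scan (%s), n = %d: %d flagged\n",
              x$method, x$n, length(x$flagged_indices)))
  if (length(x$flagged_indices))
    cat("  indices:", paste(x$flagged_indices, collapse = ", "),
        " ratios:", paste(sprintf("%.4f", x$statistic_per_flag), collapse = ", "), "\n")
  invisible(x)
}
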