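# Correlation of log10 TSH with FT4, and reclassification impact of
# replacing one RI set by another.

#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment r; two-sided p via `t = r * sqrt((n-2)/(1-r^2))`;
#' confidence interval `tanh(atanh(r) +/- z_{1-a/2}/sqrt(n-3))`. For the
#' thyroid application the caller supplies x = log10 TSH and y = FT4.
#'
#' @param x,y numeric vectors of equal length, n >= 4.
#' @param conf confidence level (default 0.95).
#' @param label optional stratum label.
#' @return object of class `correlation_result`: `label`, `r`, `ci_low`,
#'   `ci_high`, `r_squared`, `n`, `p_value`, `statistic` (the t value).
#' @examples
#' set.seed(1)
#' x <- rnorm(240); y <- -0.45 * x + rnorm(240, sd = sqrt(1 - 0.45^2))
#' pearson_fisher_ci(x, y)
#' @export
pearson_fisher_ci <- function(x, y, conf = 0.95, label = NULL) {
  ok <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 4L || length(y) != n) stop("need paired samples with n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = conf)
  r <- unname(ct$estimate)
  if (1 - abs(r) < 1e-12) stop("|r| = 1: Fisher interval undefined")
  out <- list(label = label, r = r,
              ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
              r_squared = r^2, n = n, p_value = ct$p.value,
              statistic = unname(ct$statistic))
  class(out) <- "correlation_result"
  out
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%sPearson r = %.4f, 95%% CI = %.4f to %.4f, R squared = %.4f, n = %d, p = %.3g\n",
              if (!is.null(x$label)) paste0(x$label, ": ") else "",
              x$r, x$ci_low, x$ci_high, x$r_squared, x$n, x$p_value))
  invisible(x)
}

#' Reference-interval set
#'
#' A named collection of age-banded intervals for one analyte, e.g. the
#' manufacturer's single all-ages interval or the study's three
#' age-specific intervals.
#'
#' @param analyte `"TSH"` or `"FT4"`.
#' @param bands data.frame with columns `label`, `lower_age`, `upper_age`
#'   (inclusive years, `Inf` for open-ended), `lower`, `upper` (analyte
#'   units). Bands must not overlap.
#' @param provenance e.g. `"manufacturer"` or `"study"`.
#' @return object of class `ri_set`.
#' @export
ri_set <- function(analyte, bands, provenance = "study") {
  stopifnot(is.data.frame(bands),
            all(c("label", "lower_age", "upper_age", "lower", "upper") %in% names(bands)),
            all(bands$lower <= bands$upper),
            all(bands$lower_age <= bands$upper_age))
  out <- list(analyte = analyte, bands = bands, provenance = provenance)
  class(out) <- "ri_set"
  out
}

#' Built-in reference-interval sets
#'
#' `manufacturer_ri()` returns the assay manufacturer's all-ages interval
#' (TSH 0.3-4.2 mU/L; FT4 0.9-1.7 ng/dL). `study_ri()` returns the
#' age-specific intervals the reference study derived (TSH 0.4-4.3 under
#' 60, 0.4-5.8 for 60-79, 0.4-6.7 at 80+; FT4 0.7-1.9 under 60, 0.7-1.7
#' at 60+).
#'
#' @param analyte `"TSH"` or `"FT4"`.
#' @return an [ri_set()].
#' @export
manufacturer_ri <- function(analyte = c("TSH", "FT4")) {
  analyte <- match.arg(analyte)
  b <- if (analyte == "TSH") c(0.3, 4.2) else c(0.9, 1.7)
  ri_set(analyte, data.frame(label = "all ages", lower_age = 18, upper_age = Inf,
                             lower = b[1], upper = b[2]),
         provenance = "manufacturer")
}

#' @rdname manufacturer_ri
#' @export
study_ri <- function(analyte = c("TSH", "FT4")) {
  analyte <- match.arg(analyte)
  bands <- if (analyte == "TSH") {
    data.frame(label = c("<60", "60-79", ">=80"),
               lower_age = c(18, 60, 80), upper_age = c(59, 79, Inf),
               lower = c(0.4, 0.4, 0.4), upper = c(4.3, 5.8, 6.7))
  } else {
    data.frame(label = c("<60", ">=60"),
               lower_age = c(18, 60), upper_age = c(59, Inf),
               lower = c(0.7, 0.7), upper = c(1.9, 1.7))
  }
  ri_set(analyte, bands, provenance = "study")
}

# interval (lower, upper) applying to each age; error if an age has none.
.ri_lookup <- function(set, age) {
  b <- set$bands
  idx <- rep(NA_integer_, length(age))
  for (i in seq_len(nrow(b)))
    idx[age >= b$lower_age[i] & age <= b$upper_age[i]] <- i
  if (anyNA(idx))
    stop("RI set '", set$provenance, "' has no band for age(s): ",
         paste(unique(age[is.na(idx)]), collapse = ", "))
  cbind(lower = b$lower[idx], upper = b$upper[idx])
}

#' Classify values against a reference interval
#'
#' Values strictly below the lower bound are `"below"`, strictly above
#' the upper bound `"above"`; the bounds themselves count as `"within"`
#' (reference intervals are inclusive).
#'
#' @param value numeric vector.
#' @param lower,upper interval bounds (recycled).
#' @return factor with levels below/within/above; `NA` for missing values.
#' @export
classify_values <- function(value, lower, upper) {
  out <- ifelse(is.na(value), NA_character_,
                ifelse(value < lower, "below",
                       ifelse(value > upper, "above", "within")))
  factor(out, levels = c("below", "within", "above"))
}

#' Default reporting age bands for reclassification
#'
#' @return an [age_strata()]-like data.frame with bands <60, 60-79, >=80.
#' @export
reclass_bands <- function() {
  data.frame(label = c("<60", "60-79", ">=80"),
             lower = c(18, 60, 80), upper = c(59, 79, Inf),
             stringsAsFactors = FALSE)
}

#' Reclassification table for two RI sets
#'
#' Per age band: the percentage of subjects whose analyte falls below or
#' above each RI set, and the signed differences (set B minus set A).
#' Percentages are computed on the unrounded scale; [print()] and
#' [reclassification_rounded()] reproduce the printed-table convention of
#' 1-decimal percentages with differences recomputed from the rounded
#' columns.
#'
#' @param cohort validated cohort data.frame.
#' @param ri_a,ri_b [ri_set()] objects (A is the incumbent, e.g. the
#'   manufacturer's; B the replacement).
#' @param bands reporting bands (data.frame with `label`, `lower`,
#'   `upper`); default [reclass_bands()].
#' @param analyte cohort column to classify (default `"tsh"`).
#' @return object of class `reclassification_table`: a data.frame with
#'   one row per band and columns `band`, `n` (subjects with the analyte
#'   present), `n_missing`, `pct_below_a`, `pct_below_b`, `diff_below`,
#'   `pct_above_a`, `pct_above_b`, `diff_above`, `empty` (flag for bands
#'   with no usable subjects).
#' @export
reclassification_table <- function(cohort, ri_a, ri_b, bands = reclass_bands(),
                                   analyte = "tsh") {
  stopifnot(inherits(ri_a, "ri_set"), inherits(ri_b, "ri_set"))
  value <- cohort[[analyte]]
  age <- cohort$age
  rows <- lapply(seq_len(nrow(bands)), function(i) {
    in_band <- age >= bands$lower[i] & age <= bands$upper[i]
    v <- value[in_band]; a <- age[in_band]
    present <- !is.na(v)
    n <- sum(present)
    if (n == 0L) {
      return(data.frame(band = bands$label[i], n = 0L,
                        n_missing = sum(in_band) - n,
                        pct_below_a = NA_real_, pct_below_b = NA_real_,
                        diff_below = NA_real_,
                        pct_above_a = NA_real_, pct_above_b = NA_real_,
                        diff_above = NA_real_, empty = TRUE,
                        stringsAsFactors = FALSE))
    }
    v <- v[present]; a <- a[present]
    la <- .ri_lookup(ri_a, a); lb <- .ri_lookup(ri_b, a)
    ca <- classify_values(v, la[, "lower"], la[, "upper"])
    cb <- classify_values(v, lb[, "lower"], lb[, "upper"])
    pct <- function(cl, side) 100 * mean(cl == side)
    data.frame(band = bands$label[i], n = n, n_missing = sum(in_band) - n,
               pct_below_a = pct(ca, "below"), pct_below_b = pct(cb, "below"),
               diff_below = pct(cb, "below") - pct(ca, "below"),
               pct_above_a = pct(ca, "above"), pct_above_b = pct(cb, "above"),
               diff_above = pct(cb, "above") - pct(ca, "above"),
               empty = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("reclassification_table", "data.frame")
  out
}

#' Build a reclassification table from printed percentages
#'
#' For reproducing a published table: the difference columns are computed
#' from the given (already rounded) percentages exactly.
#'
#' @param band character vector of band labels.
#' @param pct_below_a,pct_below_b,pct_above_a,pct_above_b percentages.
#' @param n optional per-band denominators.
#' @return a `reclassification_table`.
#' @export
reclassification_from_percent <- function(band, pct_below_a, pct_below_b,
                                          pct_above_a, pct_above_b, n = NA_integer_) {
  out <- data.frame(band = band, n = n, n_missing = NA_integer_,
                    pct_below_a = pct_below_a, pct_below_b = pct_below_b,
                    diff_below = pct_below_b - pct_below_a,
                    pct_above_a = pct_above_a, pct_above_b = pct_above_b,
                    diff_above = pct_above_b - pct_above_a,
                    empty = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("reclassification_table", "data.frame")
  out
}

#' Rounded (printed-style) view of a reclassification table
#'
#' Percentages rounded to 1 decimal, difference columns recomputed from
#' the rounded percentages - the convention of the published comparison
#' table.
#'
#' @param table a `reclassification_table`.
#' @param digits decimals (default 1).
#' @return data.frame.
#' @export
reclassification_rounded <- function(table, digits = 1L) {
  out <- as.data.frame(table)
  for (col in c("pct_below_a", "pct_below_b", "pct_above_a", "pct_above_b"))
    out[[col]] <- round(out[[col]], digits)
  out$diff_below <- out$pct_below_b - out$pct_below_a
  out$diff_above <- out$pct_above_b - out$pct_above_a
  out
}

#' @export
print.reclassification_table <- function(x, ...) {
  cat("Reclassification (percent below / above RI; B minus A):\n")
  print(reclassification_rounded(x)[, c("band", "n", "pct_below_a", "pct_below_b",
                                        "diff_below", "pct_above_a", "pct_above_b",
                                        "diff_above")], row.names = FALSE)
  invisible(x)
}

#' Headline reclassification impact
#'
#' The reduction in above-RI classification per elderly band
#' (`pct_above_a - pct_above_b`) and their total: the share of subjects
#' whose elevated-TSH label under RI set A is reclassified to normal
#' under set B.
#'
#' @param table a `reclassification_table`.
#' @param elderly_bands band labels to total over (default `"60-79"`,
#'   `">=80"`).
#' @return list with `per_band` (named numeric) and `total`.
#' @export
reclassification_headline <- function(table, elderly_bands = c("60-79", ">=80")) {
  idx <- match(elderly_bands, table$band)
  if (anyNA(idx)) stop("band(s) not in table: ",
                       paste(elderly_bands[is.na(idx)], collapse = ", "))
  red <- table$pct_above_a[idx] - table$pct_above_b[idx]
  names(red) <- elderly_bands
  list(per_band = red, total = sum(red))
}
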