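# ri_fit: the modelling front end.
#
# Fits age-specific nonparametric reference intervals to one analyte of a
# screened cohort: stratify by age, decide the analysis scale, test
# whether the sexes need separate intervals (Harris-Boyd), merge adjacent
# age strata whose distributions do not differ, Dixon-scan each merged
# group and estimate its central-95% percentile interval.

#' Fit age-specific reference intervals
#'
#' @param formula model formula of the form `analyte ~ age` or
#'   `analyte ~ sex + age`, naming columns of `data`. With `sex` on the
#'   right-hand side the Harris-Boyd criterion decides per-sex versus
#'   common intervals; without it a common interval is fitted directly.
#' @param data a cohort data.frame (typically the `eligible` component of
#'   [screen_cohort()]).
#' @param strata [age_strata()] defining the design strata.
#' @param coverage central coverage of the interval (default 0.95).
#' @param log10_scale `TRUE` to analyze on the log10 scale (outlier scan,
#'   group comparisons, Harris-Boyd), `NULL` (default) to decide by
#'   analyte name (TSH-like responses are log-scaled), or `"auto"` to
#'   decide by [ks_normality()] on raw versus log10 values (consumes the
#'   RNG stream).
#' @param alpha significance level for merge decisions (default 0.05).
#' @param test_family `"rank"`, `"gaussian"`, or `NULL` to follow the
#'   scale (log10-scaled analytes use rank tests, raw ones Gaussian).
#' @param dixon_method outlier scan variant, see [dixon_outliers()].
#' @param rounding reported decimals for the bounds (default 1).
#' @param adjust multiplicity adjustment for merge comparisons, see
#'   [build_merge_plan()].
#' @return object of class `ri_fit`. Key components: `intervals` (named
#'   list of [nonparametric_ri()] results per merged group, or per
#'   sex:group when partitioning was required), `merge_plan`,
#'   `sex_partition` (list of [harris_boyd_z()] decisions per stratum,
#'   `NULL` without `sex` in the formula), `outliers`, `normality`,
#'   `descriptives`, `group_bounds`.
#' @examples
#' cohort <- generate_cohort(study_cohort_config(n_per_sex = 60, seed = 7))
#' fit <- ri_fit(tsh ~ sex + age, cohort)
#' coef(fit)
#' @export
ri_fit <- function(formula, data, strata = age_strata(), coverage = 0.95,
                   log10_scale = NULL, alpha = 0.05, test_family = NULL,
                   dixon_method = c("clsi_one_third", "dixon_q"),
                   rounding = 1L, adjust = c("none", "bonferroni")) {
  cl <- match.call()
  dixon_method <- match.arg(dixon_method)
  adjust <- match.arg(adjust)
  vars <- all.vars(formula)
  analyte <- vars[1L]
  rhs <- vars[-1L]
  if (!"age" %in% rhs) stop("the right-hand side must include 'age'")
  use_sex <- "sex" %in% rhs
  bad <- setdiff(rhs, c("age", "sex"))
  if (length(bad)) stop("unsupported term(s) in formula: ", paste(bad, collapse = ", "))
  for (v in c(analyte, rhs))
    if (is.null(data[[v]])) stop("column '", v, "' not found in data")

  ok <- !is.na(data[[analyte]])
  n_missing <- sum(!ok)
  value <- as.numeric(data[[analyte]][ok])
  age <- data$age[ok]
  sex <- if (use_sex) data$sex[ok] else NULL
  stratum <- assign_stratum(age, strata)

  # analysis scale
  if (identical(log10_scale, "auto")) {
    raw_ks <- ks_normality(value)
    log_ks <- ks_normality(log10_transform(value))
    log10_scale <- !raw_ks$normal_at_alpha && log_ks$normal_at_alpha
  } else if (is.null(log10_scale)) {
    log10_scale <- grepl("tsh", analyte, ignore.case = TRUE)
  }
  avals <- if (log10_scale) log10_transform(value) else value
  unit <- if (grepl("tsh", analyte, ignore.case = TRUE)) "mU/L"
          else if (grepl("ft4", analyte, ignore.case = TRUE)) "ng/dL" else ""
  if (is.null(test_family)) test_family <- if (log10_scale) "rank" else "gaussian"

  # per-stratum descriptives (raw scale) and analysis-scale series
  split_a <- split(avals, stratum)
  split_r <- split(value, stratum)
  descriptives <- lapply(split_r, describe_series)

  # Harris-Boyd gender partition per stratum, on the analysis scale
  sex_partition <- NULL
  partition_by_sex <- FALSE
  if (use_sex) {
    sex_partition <- lapply(levels(stratum), function(sl) {
      f <- avals[stratum == sl & sex == "female"]
      m <- avals[stratum == sl & sex == "male"]
      if (length(f) < 2L || length(m) < 2L) return(NULL)
      harris_boyd_z(stratum_stats(f, "female"), stratum_stats(m, "male"))
    })
    names(sex_partition) <- levels(stratum)
    sex_partition <- Filter(Negate(is.null), sex_partition)
    partition_by_sex <- any(vapply(sex_partition, `[[`, TRUE, "partition_required"))
  }

  plan <- build_merge_plan(split_a, test_family = test_family, alpha = alpha,
                           adjust = adjust)
  bounds <- merge_plan_bounds(plan, strata)

  # Dixon scan + RI per merged group (per sex when partition is required).
  # The scan runs on the analysis scale; percentiles are estimated from
  # the surviving raw-scale values.
  est_one <- function(raw_v, a_v, label) {
    scan <- dixon_outliers(a_v, method = dixon_method)
    ri <- nonparametric_ri(raw_v[scan$kept], coverage = coverage,
                           rounding = rounding, analyte = toupper(analyte),
                           unit = unit)
    list(ri = ri, outliers = scan, label = label)
  }
  groups <- stats::setNames(plan$groups, plan$group_labels)
  intervals <- list(); outliers <- list()
  for (gl in names(groups)) {
    in_g <- stratum %in% groups[[gl]]
    if (partition_by_sex) {
      for (sx in c("female", "male")) {
        sel <- in_g & sex == sx
        key <- paste0(sx, ":", gl)
        est <- est_one(value[sel], avals[sel], key)
        intervals[[key]] <- est$ri; outliers[[key]] <- est$outliers
      }
    } else {
      est <- est_one(value[in_g], avals[in_g], gl)
      intervals[[gl]] <- est$ri; outliers[[gl]] <- est$outliers
    }
  }

  out <- list(call = cl, analyte = analyte, unit = unit,
              scale = if (log10_scale) "log10" else "raw",
              test_family = test_family, coverage = coverage, alpha = alpha,
              rounding = as.integer(rounding),
              strata = strata, n = length(value), n_missing = n_missing,
              stratum = stratum, value = value, analysis_value = avals,
              sex = sex, age = age,
              descriptives = descriptives,
              sex_partition = sex_partition,
              partition_by_sex = partition_by_sex,
              merge_plan = plan, group_bounds = bounds,
              outliers = outliers, intervals = intervals)
  class(out) <- "ri_fit"
  out
}

#' @export
print.ri_fit <- function(x, ...) {
  cat("Age-specific reference intervals for", toupper(x$analyte),
      sprintf("(central %g%%, analysis scale: %s)\n", 100 * x$coverage, x$scale))
  cat("n =", x$n, "subjects")
  if (x$n_missing) cat(" (", x$n_missing, " missing analyte excluded)", sep = "")
  cat("\nMerged age groups:", paste(x$merge_plan$group_labels, collapse = " | "), "\n")
  if (!is.null(x$sex_partition))
    cat("Sex partition required:", if (x$partition_by_sex) "yes" else "no",
        "(Harris-Boyd, critical 3)\n")
  cat("\n")
  for (key in names(x$intervals)) {
    cat(sprintf("  %-14s %s %s  (n = %d, %d outlier(s) removed)\n", key,
                format(x$intervals[[key]]), x$unit,
                x$intervals[[key]]$n_used,
                length(x$outliers[[key]]$flagged_indices)))
  }
  invisible(x)
}

#' @export
coef.ri_fit <- function(object, ...) {
  m <- t(vapply(object$intervals,
                function(ri) c(lower = ri$lower, upper = ri$upper), c(0, 0)))
  m
}

#' @export
summary.ri_fit <- function(object, ...) {
  desc <- do.call(rbind, lapply(names(object$descriptives), function(sl) {
    d <- object$descriptives[[sl]]
    data.frame(stratum = sl, n = d$n, median = d$median, q25 = d$q25,
               q75 = d$q75, min = d$min, max = d$max, mean = d$mean,
               sd = d$sd, median_ci_low = d$median_ci[["lower"]],
               median_ci_high = d$median_ci[["upper"]],
               stringsAsFactors = FALSE)
  }))
  hb <- if (!is.null(object$sex_partition)) {
    do.call(rbind, lapply(names(object$sex_partition), function(sl) {
      p <- object$sex_partition[[sl]]
      data.frame(stratum = sl, z = p$z, critical = p$critical,
                 partition_required = p$partition_required,
                 stringsAsFactors = FALSE)
    }))
  }
  out <- list(fit = object, descriptives = desc, harris_boyd = hb,
              comparisons = object$merge_plan$comparisons)
  class(out) <- "summary.ri_fit"
  out
}

#' @export
print.summary.ri_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPer-stratum descriptives (raw scale):\n")
  print(x$descriptives, row.names = FALSE, digits = 4)
  if (!is.null(x$harris_boyd)) {
    cat("\nHarris-Boyd sex comparison per stratum (analysis scale):\n")
    print(x$harris_boyd, row.names = FALSE, digits = 4)
  }
  cat("\nAdjacent-group comparisons:\n")
  print(x$comparisons, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Classify new measurements against fitted intervals
#'
#' @param object an `ri_fit`.
#' @param newdata data.frame with the analyte column (or `value`) and
#'   `age`; `sex` too when the fit partitioned by sex.
#' @param ... unused.
#' @return factor below/within/above per row.
#' @export
predict.ri_fit <- function(object, newdata, ...) {
  value <- if (!is.null(newdata[[object$analyte]])) newdata[[object$analyte]]
           else newdata$value
  if (is.null(value)) stop("newdata needs a '", object$analyte, "' or 'value' column")
  age <- newdata$age
  if (is.null(age)) stop("newdata needs an 'age' column")
  b <- object$group_bounds
  gidx <- rep(NA_integer_, length(age))
  for (i in seq_len(nrow(b))) gidx[age >= b$lower[i] & age <= b$upper[i]] <- i
  if (anyNA(gidx)) stop("age(s) outside all fitted groups: ",
                        paste(unique(age[is.na(gidx)]), collapse = ", "))
  key <- b$label[gidx]
  if (object$partition_by_sex) {
    if (is.null(newdata$sex)) stop("fit is sex-partitioned: newdata needs 'sex'")
    key <- paste0(newdata$sex, ":", key)
  }
  lower <- vapply(key, function(k) object$intervals[[k]]$lower, 0)
  upper <- vapply(key, function(k) object$intervals[[k]]$upper, 0)
  classify_values(value, lower, upper)
}

#' Simulate analyte data from a fitted interval model
#'
#' Draws synthetic measurements matching the fitted group structure: for
#' log10-scaled analytes each merged group's distribution is the
#' log10-normal whose central interval equals the fitted (unrounded)
#' bounds, via [calibrate_lognormal_from_bounds()]; for raw-scale
#' analytes a normal with the group's sample mean and SD.
#'
#' @param object an `ri_fit`.
#' @param nsim number of replicate cohorts.
#' @param seed optional integer seed (restores the RNG state afterwards,
#'   like [stats::simulate()]).
#' @param ... unused.
#' @return data.frame with `group` (and the subject counts of the fitted
#'   groups) plus columns `sim_1 .. sim_nsim`.
#' @export
simulate.ri_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  if (object$partition_by_sex)
    stop("simulate() supports unpartitioned fits only")
  groups <- stats::setNames(object$merge_plan$groups, object$merge_plan$group_labels)
  per_group <- lapply(names(groups), function(gl) {
    sel <- object$stratum %in% groups[[gl]]
    n <- sum(sel)
    ri <- object$intervals[[gl]]
    draws <- matrix(NA_real_, n, nsim)
    if (object$scale == "log10") {
      pars <- calibrate_lognormal_from_bounds(ri$lower_raw, ri$upper_raw)
      for (j in seq_len(nsim))
        draws[, j] <- 10^stats::rnorm(n, pars[["tsh_log10_mu"]],
                                      pars[["tsh_log10_sigma"]])
    } else {
      v <- object$value[sel]
      for (j in seq_len(nsim))
        draws[, j] <- stats::rnorm(n, mean(v), stats::sd(v))
    }
    cbind(data.frame(group = gl, stringsAsFactors = FALSE),
          as.data.frame(draws))
  })
  out <- do.call(rbind, per_group)
  names(out)[-1L] <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot fitted reference intervals
#'
#' Strip/box display of the raw analyte by design stratum with the fitted
#' merged-group interval bounds overlaid.
#'
#' @param x an `ri_fit`.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.ri_fit <- function(x, ...) {
  graphics::boxplot(x$value ~ x$stratum, xlab = "age stratum",
                    ylab = paste0(toupper(x$analyte), " (", x$unit, ")"),
                    log = if (x$scale == "log10") "y" else "", ...)
  b <- x$group_bounds
  k <- nrow(x$strata)
  for (i in seq_len(nrow(b))) {
    members <- which(x$strata$label %in% x$merge_plan$groups[[i]])
    x0 <- min(members) - 0.4; x1 <- max(members) + 0.4
    key <- if (x$partition_by_sex) paste0("female:", b$label[i]) else b$label[i]
    ri <- x$intervals[[key]]
    graphics::segments(x0, ri$lower, x1, ri$lower, col = "red3", lwd = 2)
    graphics::segments(x0, ri$upper, x1, ri$upper, col = "red3", lwd = 2)
  }
  invisible(x)
}

#' Fitted intervals as an RI set
#'
#' Converts a fitted model into an [ri_set()] usable in
#' [reclassification_table()]. For sex-partitioned fits the per-sex
#' bounds are widened to their union.
#'
#' @param fit an `ri_fit`.
#' @param lower_age age from which the set should apply (default the
#'   first stratum's lower bound; extend downwards with e.g. 18 to cover
#'   younger eligible subjects).
#' @return an [ri_set()] with provenance `"fitted"`.
#' @export
as_ri_set <- function(fit, lower_age = NULL) {
  stopifnot(inherits(fit, "ri_fit"))
  b <- fit$group_bounds
  lo <- up <- numeric(nrow(b))
  for (i in seq_len(nrow(b))) {
    keys <- if (fit$partition_by_sex)
      paste0(c("female", "male"), ":", b$label[i]) else b$label[i]
    lo[i] <- min(vapply(keys, function(k) fit$intervals[[k]]$lower, 0))
    up[i] <- max(vapply(keys, function(k) fit$intervals[[k]]$upper, 0))
  }
  bands <- data.frame(label = b$label, lower_age = b$lower, upper_age = b$upper,
                      lower = lo, upper = up, stringsAsFactors = FALSE)
  if (!is.null(lower_age)) bands$lower_age[1] <- lower_age
  ri_set(toupper(fit$analyte), bands, provenance = "fitted")
}
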