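# End-to-end pipeline: ingest or simulate a cohort, screen it, fit
# age-specific intervals for TSH and FT4, correlate the analytes per
# stratum, and quantify the reclassification impact of replacing the
# manufacturer's intervals with the fitted ones. Every stage's artifact
# is written as plain structured text so a run can be audited.

#' Pipeline configuration
#'
#' @param input either a file path to a cohort table (.csv/.tsv) or a
#'   [cohort_config()] for the synthetic generator.
#' @param rules [screening_rules()].
#' @param strata [age_strata()].
#' @param alpha significance level for merge decisions.
#' @param coverage RI central coverage.
#' @param dixon_method outlier scan variant.
#' @param rounding reported bound decimals.
#' @param seed integer seed driving every stochastic stage (generator
#'   substreams and Monte-Carlo p-values).
#' @param out_dir directory for stage artifacts, or `NULL` to keep the
#'   run in memory only.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, rules = screening_rules(),
                            strata = age_strata(), alpha = 0.05,
                            coverage = 0.95,
                            dixon_method = "clsi_one_third",
                            rounding = 1L, seed = 1L, out_dir = NULL) {
  if (is.character(input)) {
    if (!file.exists(input)) stop("input file does not exist: ", input)
  } else if (!inherits(input, "cohort_config")) {
    stop("input must be a file path or a cohort_config")
  }
  out <- list(input = input, rules = rules, strata = strata, alpha = alpha,
              coverage = coverage, dixon_method = dixon_method,
              rounding = rounding, seed = as.integer(seed), out_dir = out_dir)
  class(out) <- "pipeline_config"
  out
}

.write_artifact <- function(dir, name, obj) {
  if (is.null(dir)) return(invisible(NULL))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, name)
  if (grepl("\\.csv$", name)) {
    utils::write.csv(obj, path, row.names = FALSE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  invisible(path)
}

#' Run the full reference-interval pipeline
#'
#' Stages, in fixed order: ingest/simulate, screen, per-stratum
#' descriptives, TSH fit (log10 scale, rank tests), FT4 fit (raw scale,
#' Gaussian tests), per-stratum log10(TSH)-FT4 correlations, and
#' reclassification of the cohort's TSH against the manufacturer's
#' all-ages interval versus the fitted age-specific set. Identical
#' configuration and seed give an identical report (timestamp aside).
#'
#' @param config a [pipeline_config()].
#' @return object of class `run_report`; see its components.
#' @examples
#' cfg <- pipeline_config(study_cohort_config(n_per_sex = 60, seed = 3), seed = 3)
#' report <- run_pipeline(cfg)
#' report$tsh_fit
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir <- config$out_dir
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  set.seed(config$seed)

  cohort <- stage("ingest", {
    if (is.character(config$input)) read_cohort(config$input)
    else generate_cohort(config$input, rules = config$rules)
  })
  .write_artifact(dir, "01_cohort.csv", cohort)

  screened <- stage("screen", screen_cohort(cohort, config$rules))
  .write_artifact(dir, "02_screening.json",
                  list(n_total = nrow(cohort),
                       n_eligible = nrow(screened$eligible),
                       n_excluded = screened$n_excluded,
                       summary = as.list(screened$summary),
                       exclusions = screened$reasons))
  eligible <- screened$eligible
  if (nrow(eligible) == 0L) stop("pipeline stage 'screen' left no eligible subjects")

  tsh_fit <- stage("tsh_fit",
    ri_fit(tsh ~ sex + age, eligible, strata = config$strata,
           coverage = config$coverage, alpha = config$alpha,
           dixon_method = config$dixon_method, rounding = config$rounding))
  ft4_fit <- stage("ft4_fit",
    ri_fit(ft4 ~ sex + age, eligible, strata = config$strata,
           coverage = config$coverage, alpha = config$alpha,
           dixon_method = config$dixon_method, rounding = config$rounding))
  .write_artifact(dir, "03_tsh_fit.json", .fit_payload(tsh_fit))
  .write_artifact(dir, "04_ft4_fit.json", .fit_payload(ft4_fit))

  correlations <- stage("correlations", {
    st <- assign_stratum(eligible$age, config$strata)
    lapply(levels(st), function(sl) {
      sel <- st == sl & !is.na(eligible$tsh) & !is.na(eligible$ft4)
      if (sum(sel) < 4L) return(NULL)
      pearson_fisher_ci(log10(eligible$tsh[sel]), eligible$ft4[sel], label = sl)
    })
  })
  correlations <- Filter(Negate(is.null), correlations)
  cor_df <- do.call(rbind, lapply(correlations, function(cr)
    data.frame(stratum = cr$label, r = cr$r, ci_low = cr$ci_low,
               ci_high = cr$ci_high, r_squared = cr$r_squared, n = cr$n,
               p_value = cr$p_value, stringsAsFactors = FALSE)))
  .write_artifact(dir, "05_correlations.csv", cor_df)

  reclass <- stage("reclassification", {
    fitted_set <- as_ri_set(tsh_fit, lower_age = 18)
    reclassification_table(eligible, manufacturer_ri("TSH"), fitted_set,
                           bands = .bands_from_fit(tsh_fit))
  })
  .write_artifact(dir, "06_reclassification.csv",
                  reclassification_rounded(reclass))

  report <- list(
    config = config,
    n_total = nrow(cohort), n_eligible = nrow(eligible),
    exclusion_summary = screened$summary,
    exclusion_log = screened$reasons,
    descriptives = list(tsh = tsh_fit$descriptives, ft4 = ft4_fit$descriptives),
    tsh_fit = tsh_fit, ft4_fit = ft4_fit,
    correlations = cor_df,
    reclassification = reclass,
    version = as.character(utils::packageVersion("thyroRI")),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  class(report) <- "run_report"
  .write_artifact(dir, "07_report.json", .report_payload(report))
  report
}

# reporting bands derived from the fitted merged groups, extended down to
# the eligibility floor so every eligible age is covered
.bands_from_fit <- function(fit) {
  b <- merge_plan_bounds(fit$merge_plan, fit$strata)
  b$lower[1] <- 18
  names(b) <- c("label", "lower", "upper")
  b
}

# machine-readable payloads (plain lists; deterministic given config+seed)
.fit_payload <- function(fit) {
  list(analyte = fit$analyte, scale = fit$scale, n = fit$n,
       groups = fit$merge_plan$group_labels,
       partition_by_sex = fit$partition_by_sex,
       comparisons = fit$merge_plan$comparisons,
       intervals = lapply(fit$intervals, function(ri)
         list(lower = ri$lower, upper = ri$upper, n_used = ri$n_used,
              coverage = ri$coverage, method = ri$method)),
       outliers_removed = vapply(fit$outliers,
                                 function(o) length(o$flagged_indices), 0L))
}

.report_payload <- function(report) {
  list(version = report$version, seed = report$seed,
       n_total = report$n_total, n_eligible = report$n_eligible,
       exclusion_summary = as.list(report$exclusion_summary),
       tsh = .fit_payload(report$tsh_fit),
       ft4 = .fit_payload(report$ft4_fit),
       correlations = report$correlations,
       reclassification = reclassification_rounded(report$reclassification))
}

#' @export
print.run_report <- function(x, ...) {
  cat("thyroRI pipeline run (seed ", x$seed, ", v", x$version, ")\n", sep = "")
  cat(x$n_total, "subjects,", x$n_eligible, "eligible after screening\n\n")
  print(x$tsh_fit); cat("\n"); print(x$ft4_fit)
  cat("\n"); print(x$reclassification)
  invisible(x)
}

#' Render report tables
#'
#' Human-readable data.frames mirroring the study's result tables:
#' per-stratum analyte descriptives with the assumed merged-group RIs,
#' the fitted intervals, the per-stratum correlation table, and the
#' reclassification comparison with 1-decimal percentages.
#'
#' @param report a `run_report`.
#' @return named list of data.frames: `tsh_descriptives`,
#'   `ft4_descriptives`, `reference_intervals`, `correlations`,
#'   `reclassification`.
#' @export
render_tables <- function(report) {
  stopifnot(inherits(report, "run_report"))
  need <- c("descriptives", "tsh_fit", "ft4_fit", "correlations",
            "reclassification")
  miss <- need[vapply(need, function(f) is.null(report[[f]]), TRUE)]
  if (length(miss)) stop("incomplete report: missing ", paste(miss, collapse = ", "))
  desc_tab <- function(fit) {
    d <- summary(fit)$descriptives
    num <- vapply(d, is.numeric, TRUE)
    d[num] <- lapply(d[num], round, 2)
    d
  }
  ri_tab <- do.call(rbind, lapply(list(report$tsh_fit, report$ft4_fit), function(fit) {
    data.frame(analyte = toupper(fit$analyte),
               group = names(fit$intervals),
               interval = vapply(fit$intervals, format, ""),
               unit = fit$unit,
               n_used = vapply(fit$intervals, `[[`, 0L, "n_used"),
               stringsAsFactors = FALSE)
  }))
  rownames(ri_tab) <- NULL
  cor_tab <- report$correlations
  num <- vapply(cor_tab, is.numeric, TRUE)
  cor_tab[num] <- lapply(cor_tab[num], round, 4)
  list(tsh_descriptives = desc_tab(report$tsh_fit),
       ft4_descriptives = desc_tab(report$ft4_fit),
       reference_intervals = ri_tab,
       correlations = cor_tab,
       reclassification = reclassification_rounded(report$reclassification))
}
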