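# Eligibility screening of a reference cohort.
#
# A subject enters the reference population only if no exclusion rule
# fires: TSH inside the screening band (default 0.1-10.0 mU/L, outside
# which overt dysfunction is too likely), thyroid autoantibodies below the
# assay positivity cutoffs (TPOAb < 34 IU/mL, TGAb < 115 IU/mL), no
# excluded questionnaire flag (thyroid or family thyroid history, goiter,
# smoking, hospitalization or iodine exposure in the last six months,
# pregnancy), and no interfering medication.

.norm_name <- function(x) gsub("\\s+", " ", tolower(trimws(x)))

#' Interfering-medication list
#'
#' Reads the packaged list of medications and other drugs with known
#' analytical or physiological interference on TSH/FT4 measurement. Users
#' can substitute their own list (one name per line, `#` comments allowed).
#'
#' @param path optional path to a replacement list.
#' @return character vector of medication names.
#' @export
interfering_medications <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "interfering_medications.txt",
                        package = "thyroRI", mustWork = TRUE)
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Screening rule set
#'
#' Bundles the eligibility rules applied to every candidate subject.
#'
#' @param tsh_band numeric length-2: the TSH screening band in mU/L;
#'   values outside it (strictly below the low or above the high bound)
#'   exclude the subject.
#' @param tpoab_cutoff,tgab_cutoff antibody positivity cutoffs in IU/mL;
#'   titres `>= cutoff` are positive and exclude (the assay defines
#'   negatives as scoring *lower than* the cutoff).
#' @param medications character vector of interfering medication names;
#'   matching is case-insensitive, whitespace-normalized, exact-name.
#' @param excluded_flags questionnaire flags whose truth excludes.
#' @param missing_antibody_policy what to do when an antibody titre needed
#'   by an active rule is missing: `"insufficient_data"` sets the subject
#'   aside (default; inclusion required demonstrably negative antibodies),
#'   `"ignore"` lets the missing rule pass.
#' @return object of class `screening_rules`.
#' @export
screening_rules <- function(tsh_band = c(0.1, 10.0),
                            tpoab_cutoff = 34,
                            tgab_cutoff = 115,
                            medications = interfering_medications(),
                            excluded_flags = .cohort_flags,
                            missing_antibody_policy = c("insufficient_data", "ignore")) {
  stopifnot(length(tsh_band) == 2L, tsh_band[1] < tsh_band[2],
            tpoab_cutoff > 0, tgab_cutoff > 0)
  excluded_flags <- match.arg(excluded_flags, .cohort_flags, several.ok = TRUE)
  out <- list(tsh_band = as.numeric(tsh_band),
              tpoab_cutoff = tpoab_cutoff, tgab_cutoff = tgab_cutoff,
              medications = .norm_name(medications),
              excluded_flags = excluded_flags,
              missing_antibody_policy = match.arg(missing_antibody_policy))
  class(out) <- "screening_rules"
  out
}

# Reason codes for one subject (character(0) when eligible).
.screen_reasons <- function(record, rules) {
  reasons <- character()
  if (is.na(record$tsh)) {
    reasons <- c(reasons, "insufficient_data")
  } else if (record$tsh < rules$tsh_band[1] || record$tsh > rules$tsh_band[2]) {
    reasons <- c(reasons, "tsh_out_of_screen_band")
  }
  ab <- function(value, cutoff, code) {
    if (is.na(value)) {
      if (rules$missing_antibody_policy == "insufficient_data") "insufficient_data"
      else character()
    } else if (value >= cutoff) code else character()
  }
  reasons <- c(reasons, ab(record$tpoab, rules$tpoab_cutoff, "tpoab_positive"))
  reasons <- c(reasons, ab(record$tgab, rules$tgab_cutoff, "tgab_positive"))
  for (f in rules$excluded_flags)
    if (isTRUE(record[[f]])) reasons <- c(reasons, paste0("flag_", f))
  meds <- .norm_name(strsplit(record$medications, ";", fixed = TRUE)[[1L]])
  if (any(meds %in% rules$medications))
    reasons <- c(reasons, "interfering_medication")
  unique(reasons)
}

#' Screen a single subject
#'
#' @param record one-row cohort data.frame (a subject record).
#' @param rules a [screening_rules()] object.
#' @return list with `subject_id`, `eligible` (TRUE iff no rule fired) and
#'   `reasons`, a character vector of machine-readable reason codes, one
#'   per violated rule. A missing TSH or antibody titre yields the code
#'   `"insufficient_data"` rather than an eligibility verdict on the rule.
#' @export
screen_subject <- function(record, rules = screening_rules()) {
  stopifnot(is.data.frame(record), nrow(record) == 1L,
            inherits(rules, "screening_rules"))
  reasons <- .screen_reasons(record, rules)
  list(subject_id = record$id, eligible = length(reasons) == 0L,
       reasons = reasons)
}

#' Screen a cohort
#'
#' Applies [screen_subject()] to every record and partitions the cohort
#' into eligible and excluded subsets.
#'
#' @param cohort validated cohort data.frame (nonempty).
#' @param rules a [screening_rules()] object.
#' @return object of class `screening_result`: list with
#'   \describe{
#'     \item{eligible}{data.frame of eligible subjects}
#'     \item{excluded}{data.frame of excluded subjects}
#'     \item{reasons}{data.frame `subject_id`, `reasons` (";"-joined) for
#'       every excluded subject}
#'     \item{summary}{named integer vector: exclusions per reason code,
#'       counted with multiplicity (a subject violating two rules counts
#'       once under each)}
#'     \item{n_excluded}{number of excluded subjects}
#'   }
#' @export
screen_cohort <- function(cohort, rules = screening_rules()) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop("cohort must be a nonempty data.frame")
  cohort <- validate_cohort(cohort)
  reason_list <- lapply(seq_len(nrow(cohort)),
                        function(i) .screen_reasons(cohort[i, , drop = FALSE], rules))
  ok <- lengths(reason_list) == 0L
  all_codes <- unlist(reason_list)
  summary <- if (length(all_codes)) {
    tab <- table(all_codes)
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(integer(), character())
  out <- list(
    eligible = cohort[ok, , drop = FALSE],
    excluded = cohort[!ok, , drop = FALSE],
    reasons = data.frame(
      subject_id = cohort$id[!ok],
      reasons = vapply(reason_list[!ok], paste, "", collapse = ";"),
      stringsAsFactors = FALSE),
    summary = summary,
    n_excluded = sum(!ok))
  class(out) <- "screening_result"
  out
}

#' @export
print.screening_result <- function(x, ...) {
  cat("Cohort screening:", nrow(x$eligible), "eligible,",
      x$n_excluded, "excluded\n")
  if (length(x$summary)) {
    cat("Exclusions by reason (with multiplicity):\n")
    for (r in names(x$summary)) cat("  ", r, ": ", x$summary[[r]], "\n", sep = "")
  }
  invisible(x)
}
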