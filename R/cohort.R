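# Cohort data model and delimited-text I/O.
#
# A cohort is a plain data.frame with one validated row per subject. The
# fixed schema below is the on-disk column order; `medications` holds a
# ";"-separated list of free-text drug names ("" = none), and missing
# analytes are empty cells, never zero.

.cohort_analytes <- c("tsh", "ft4", "tpoab", "tgab")
.cohort_flags <- c("thyroid_history", "family_thyroid_history", "goiter",
                   "smoker", "hospitalized_6mo", "pregnant",
                   "iodine_exposure_6mo")

#' Cohort column schema
#'
#' @return character vector of required column names, in canonical order:
#'   `id`, `sex`, `age`, the four analytes (`tsh` mU/L, `ft4` ng/dL,
#'   `tpoab` IU/mL, `tgab` IU/mL), seven boolean questionnaire flags, and
#'   `medications`.
#' @export
cohort_schema <- function() {
  c("id", "sex", "age", .cohort_analytes, .cohort_flags, "medications")
}

#' Validate a cohort data.frame
#'
#' Checks the subject-record invariants: complete schema, `sex` in
#' \{female, male\}, integer `age >= 18`, strictly positive TSH/FT4 and
#' non-negative antibody titres where present, logical flags, and
#' `pregnant` only for females.
#'
#' @param cohort data.frame to validate.
#' @return the cohort, invisibly, with columns coerced to canonical types.
#' @export
validate_cohort <- function(cohort) {
  miss <- setdiff(cohort_schema(), names(cohort))
  if (length(miss))
    stop("schema error: missing required column(s): ", paste(miss, collapse = ", "))
  cohort <- cohort[, cohort_schema()]
  cohort$id <- as.character(cohort$id)
  if (anyDuplicated(cohort$id)) stop("duplicate subject id")
  if (!all(cohort$sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'")
  if (any(is.na(cohort$age)) || any(cohort$age != as.integer(cohort$age)))
    stop("age must be a whole number of years")
  cohort$age <- as.integer(cohort$age)
  if (any(cohort$age < 18L)) stop("age must be >= 18")
  for (a in c("tsh", "ft4")) {
    v <- cohort[[a]]
    if (any(!is.na(v) & v <= 0)) stop(a, " must be strictly positive when present")
    cohort[[a]] <- as.numeric(v)
  }
  for (a in c("tpoab", "tgab")) {
    v <- cohort[[a]]
    if (any(!is.na(v) & v < 0)) stop(a, " must be non-negative when present")
    cohort[[a]] <- as.numeric(v)
  }
  for (f in .cohort_flags) {
    if (!is.logical(cohort[[f]]) || anyNA(cohort[[f]]))
      stop("flag '", f, "' must be TRUE/FALSE with no missing values")
  }
  if (any(cohort$pregnant & cohort$sex != "female"))
    stop("pregnant implies sex = female")
  cohort$medications <- ifelse(is.na(cohort$medications), "",
                               as.character(cohort$medications))
  invisible(cohort)
}

.cohort_sep <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") "," else if (ext %in% c("tsv", "txt")) "\t"
  else stop("cannot infer delimiter from extension '.", ext, "' (use .csv or .tsv)")
}

#' Read a subject cohort from delimited text
#'
#' Reads a UTF-8 comma- or tab-separated table (delimiter auto-detected from
#' the extension) with a header row naming every column of
#' [cohort_schema()]. Empty cells are missing values. Malformed numeric
#' cells raise an error naming the offending data row.
#'
#' @param path file path (.csv or .tsv).
#' @return validated cohort data.frame.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = .cohort_sep(path), header = TRUE,
                           colClasses = "character", na.strings = NULL,
                           check.names = FALSE, quote = "\"",
                           fileEncoding = "UTF-8")
  miss <- setdiff(cohort_schema(), names(raw))
  if (length(miss))
    stop("schema error: missing required column(s): ", paste(miss, collapse = ", "))
  parse_num <- function(col) {
    x <- trimws(raw[[col]])
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & nzchar(x) & is.na(out))
    if (length(bad))
      stop("malformed numeric value in column '", col, "' at row ",
           paste(bad, collapse = ", "), " ('", x[bad[1L]], "')")
    out[x == ""] <- NA_real_
    out
  }
  parse_flag <- function(col) {
    x <- toupper(trimws(raw[[col]]))
    out <- rep(NA, length(x))
    out[x %in% c("TRUE", "T", "1", "YES")] <- TRUE
    out[x %in% c("FALSE", "F", "0", "NO")] <- FALSE
    bad <- which(is.na(out))
    if (length(bad))
      stop("malformed logical value in column '", col, "' at row ",
           paste(bad, collapse = ", "))
    out
  }
  cohort <- data.frame(id = raw$id, sex = trimws(raw$sex),
                       age = parse_num("age"), stringsAsFactors = FALSE)
  for (a in .cohort_analytes) cohort[[a]] <- parse_num(a)
  for (f in .cohort_flags) cohort[[f]] <- parse_flag(f)
  cohort$medications <- raw$medications
  validate_cohort(cohort)
}

#' Write a subject cohort to delimited text
#'
#' Inverse of [read_cohort()]: missing analytes become empty cells so a
#' round trip preserves every field.
#'
#' @param cohort validated cohort data.frame.
#' @param path output path (.csv or .tsv decides the delimiter).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  utils::write.table(cohort, path, sep = .cohort_sep(path), na = "",
                     row.names = FALSE, quote = which(names(cohort) == "medications"),
                     fileEncoding = "UTF-8")
  invisible(path)
}
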