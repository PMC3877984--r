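#' Age strata definitions
#'
#' Constructs the set of age strata used to stratify a reference cohort.
#' The default mirrors the recruitment design of decade bands from 50
#' upwards, one wide young-adult band, and an open-ended band for the very
#' old: 20-49, 50-59, 60-69, 70-79 and >=80 years. Bounds are closed
#' integer ranges; a subject on their 80th birthday belongs to ">=80".
#'
#' @param lower integer vector of inclusive lower bounds (years).
#' @param upper integer vector of inclusive upper bounds; use `Inf` for an
#'   open-ended last stratum.
#' @param labels optional character labels; derived from the bounds when
#'   omitted.
#' @return An object of class `age_strata`: a data.frame with columns
#'   `label`, `lower`, `upper`.
#' @examples
#' age_strata()
#' @export
age_strata <- function(lower = c(20L, 50L, 60L, 70L, 80L),
                       upper = c(49L, 59L, 69L, 79L, Inf),
                       labels = NULL) {
  if (length(lower) != length(upper) || length(lower) == 0L)
    stop("'lower' and 'upper' must be nonempty and of equal length")
  if (any(lower > upper)) stop("each stratum needs lower <= upper")
  if (is.unsorted(lower, strictly = TRUE)) stop("strata must be in increasing age order")
  if (any(upper[-length(upper)] + 1L != lower[-1L]))
    stop("strata must be contiguous and disjoint")
  if (is.null(labels)) {
    labels <- ifelse(is.finite(upper), paste0(lower, "-", upper), paste0(">=", lower))
  }
  out <- data.frame(label = labels, lower = lower, upper = upper,
                    stringsAsFactors = FALSE)
  class(out) <- c("age_strata", "data.frame")
  out
}

#' Assign subjects to age strata
#'
#' Maps integer ages onto the unique stratum containing them. Ages below the
#' design (younger than the first stratum's lower bound) are an error, since
#' such subjects were never recruited.
#'
#' @param age integer vector of ages in years.
#' @param strata an [age_strata()] object.
#' @return a factor of stratum labels, levels in age order.
#' @examples
#' assign_stratum(c(49, 50, 80), age_strata())
#' @export
assign_stratum <- function(age, strata = age_strata()) {
  stopifnot(inherits(strata, "age_strata"))
  if (length(age) == 0L) return(factor(character(), levels = strata$label))
  if (any(is.na(age))) stop("age must not be missing")
  idx <- rep(NA_integer_, length(age))
  for (i in seq_len(nrow(strata))) {
    hit <- age >= strata$lower[i] & age <= strata$upper[i]
    idx[hit] <- i
  }
  if (anyNA(idx)) {
    bad <- unique(age[is.na(idx)])
    stop("out_of_design: age(s) outside all strata: ", paste(bad, collapse = ", "))
  }
  factor(strata$label[idx], levels = strata$label)
}
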