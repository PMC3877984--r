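# Seeded synthetic-cohort generator.
#
# Each stratum x sex cell draws (log10 TSH, FT4) from a bivariate normal
# with the configured means, SDs and correlation rho, then exponentiates
# the TSH coordinate; correlation is imposed between log10 TSH and FT4
# (not raw TSH), matching how the analysis correlates the analytes. A
# configurable fraction of subjects is contaminated with exactly one
# exclusion-triggering mechanism so screening has something to find.

.contam_mechanisms <- c("high_tsh", "antibody_positive", "interfering_medication",
                        "recent_hospitalization", "smoker")

#' Per-stratum generator configuration
#'
#' @param stratum stratum label (must match a label of the cohort's
#'   [age_strata()]).
#' @param n_per_sex subjects to draw per sex (default 120, the recruitment
#'   target per cell).
#' @param tsh_log10_mu,tsh_log10_sigma mean and SD of log10 TSH
#'   (dimensionless); see [calibrate_lognormal()].
#' @param ft4_mean,ft4_sd mean and SD of FT4 in ng/dL.
#' @param rho correlation between log10 TSH and FT4, in (-1, 1); thyroid
#'   physiology makes it negative (the pituitary raises TSH as FT4 falls).
#' @param contamination_fraction proportion in \[0, 1) of subjects given an
#'   exclusion-triggering feature.
#' @return object of class `stratum_config`.
#' @export
stratum_config <- function(stratum, n_per_sex = 120L,
                           tsh_log10_mu, tsh_log10_sigma,
                           ft4_mean, ft4_sd, rho = -0.45,
                           contamination_fraction = 0) {
  stopifnot(n_per_sex >= 0, tsh_log10_sigma >= 0, ft4_sd >= 0,
            rho > -1, rho < 1,
            contamination_fraction >= 0, contamination_fraction < 1)
  out <- list(stratum = as.character(stratum), n_per_sex = as.integer(n_per_sex),
              tsh_log10_mu = tsh_log10_mu, tsh_log10_sigma = tsh_log10_sigma,
              ft4_mean = ft4_mean, ft4_sd = ft4_sd, rho = rho,
              contamination_fraction = contamination_fraction)
  class(out) <- "stratum_config"
  out
}

#' Cohort generator configuration
#'
#' @param strata_configs list of [stratum_config()] objects, in age order.
#' @param seed integer master seed; per-cell substreams are derived
#'   deterministically from (seed, stratum index, sex).
#' @param strata the [age_strata()] the labels refer to.
#' @param contamination_mix named non-negative weights over the
#'   contamination mechanisms `high_tsh`, `antibody_positive`,
#'   `interfering_medication`, `recent_hospitalization`, `smoker`;
#'   normalized to sum to 1.
#' @param age_cap oldest age drawn in an open-ended stratum (default 95).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(strata_configs, seed = 1L, strata = age_strata(),
                          contamination_mix = NULL, age_cap = 95L) {
  stopifnot(length(strata_configs) >= 1L,
            all(vapply(strata_configs, inherits, TRUE, "stratum_config")))
  labs <- vapply(strata_configs, `[[`, "", "stratum")
  if (!all(labs %in% strata$label))
    stop("unknown stratum label(s): ", paste(setdiff(labs, strata$label), collapse = ", "))
  if (is.null(contamination_mix))
    contamination_mix <- stats::setNames(rep(1 / 5, 5), .contam_mechanisms)
  stopifnot(setequal(names(contamination_mix), .contam_mechanisms),
            all(contamination_mix >= 0), sum(contamination_mix) > 0)
  contamination_mix <- contamination_mix[.contam_mechanisms] / sum(contamination_mix)
  out <- list(strata_configs = strata_configs, seed = as.integer(seed),
              strata = strata, contamination_mix = contamination_mix,
              age_cap = as.integer(age_cap))
  class(out) <- "cohort_config"
  out
}

#' Generator configuration calibrated to the published study summaries
#'
#' Builds the five-stratum world the analysis assumes: per-decade log10
#' TSH sigma from the printed 25th/75th TSH percentiles, mu from the
#' merged-group assumed medians (1.5 mU/L under 60, 1.7 for 60-79, 2.0 at
#' 80+; the per-decade median rows are not unambiguously printed), FT4
#' mean +/- SD from the assumed-for-both-genders row, and the per-stratum
#' log10(TSH)-FT4 Pearson correlations as reported.
#'
#' @param n_per_sex subjects per sex per stratum (default 120, as recruited).
#' @param seed master seed.
#' @param contamination_fraction fraction of exclusion-triggering subjects
#'   (default 0: a clean reference population).
#' @inheritParams cohort_config
#' @return a [cohort_config()] object.
#' @export
study_cohort_config <- function(n_per_sex = 120L, seed = 1L,
                                contamination_fraction = 0,
                                contamination_mix = NULL) {
  labs <- age_strata()$label
  med <- c(1.5, 1.5, 1.7, 1.7, 2.0)
  q25 <- c(1.1, 1.2, 1.7, 1.7, 2.0)
  q75 <- c(2.2, 2.6, 2.8, 3.0, 3.5)
  ft4_mean <- c(1.2, 1.2, 1.1, 1.1, 1.1)
  ft4_sd <- c(0.3, 0.3, 0.2, 0.2, 0.2)
  rho <- c(-0.4641, -0.3862, -0.4653, -0.4946, -0.3951)
  cfgs <- lapply(seq_along(labs), function(i) {
    pars <- calibrate_lognormal(median = max(q25[i], min(med[i], q75[i])),
                                q25 = q25[i], q75 = q75[i])
    stratum_config(labs[i], n_per_sex = n_per_sex,
                   tsh_log10_mu = pars[["tsh_log10_mu"]],
                   tsh_log10_sigma = pars[["tsh_log10_sigma"]],
                   ft4_mean = ft4_mean[i], ft4_sd = ft4_sd[i], rho = rho[i],
                   contamination_fraction = contamination_fraction)
  })
  cohort_config(cfgs, seed = seed, contamination_mix = contamination_mix)
}

# Deterministic 31-bit substream seed from (seed, stratum index, sex index).
.substream_seed <- function(seed, i, s) {
  as.integer((as.double(seed) * 48271 + i * 7919 + s * 104729) %% 2147483629)
}

#' Generate a synthetic subject cohort
#'
#' Identical configuration and seed give byte-identical cohorts. Clean
#' subjects are constructed to pass [screen_cohort()] under the default
#' rules: TSH draws falling outside the screening band (a rare tail event)
#' are redrawn, antibody titres are drawn below the positivity cutoffs,
#' all flags are FALSE and no medication is assigned. Contaminated
#' subjects receive exactly one mechanism sampled from the configured mix.
#'
#' @param config a [cohort_config()] object.
#' @param rules the [screening_rules()] the clean draws must satisfy
#'   (supplies the TSH band, antibody cutoffs and medication list).
#' @return validated cohort data.frame, ordered by stratum then sex.
#' @examples
#' cohort <- generate_cohort(study_cohort_config(n_per_sex = 30, seed = 42))
#' table(assign_stratum(cohort$age), cohort$sex)
#' @export
generate_cohort <- function(config, rules = screening_rules()) {
  stopifnot(inherits(config, "cohort_config"))
  strata <- config$strata
  blocks <- list()
  counter <- 0L
  for (i in seq_along(config$strata_configs)) {
    sc <- config$strata_configs[[i]]
    srow <- strata[strata$label == sc$stratum, ]
    hi_age <- if (is.finite(srow$upper)) srow$upper else config$age_cap
    for (s in 1:2) {
      sex <- c("female", "male")[s]
      n <- sc$n_per_sex
      if (n == 0L) next
      seed_is <- .substream_seed(config$seed, i, s)
      block <- .generate_cell(sc, n, sex, srow$lower, hi_age, seed_is,
                              config$contamination_mix, rules)
      block$id <- sprintf("S%05d", counter + seq_len(n))
      counter <- counter + n
      blocks[[length(blocks) + 1L]] <- block
    }
  }
  if (!length(blocks)) {
    empty <- data.frame(id = character(), sex = character(), age = integer(),
                        tsh = numeric(), ft4 = numeric(), tpoab = numeric(),
                        tgab = numeric(), stringsAsFactors = FALSE)
    for (f in .cohort_flags) empty[[f]] <- logical()
    empty$medications <- character()
    return(empty)
  }
  out <- do.call(rbind, blocks)
  out <- out[, cohort_schema()]
  rownames(out) <- NULL
  validate_cohort(out)
  out
}

.generate_cell <- function(sc, n, sex, lo_age, hi_age, seed, mix, rules) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  age <- sample(lo_age:hi_age, n, replace = TRUE)
  # bivariate normal via 2x2 Cholesky: x = log10 TSH, y = FT4
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  ltsh <- sc$tsh_log10_mu + sc$tsh_log10_sigma * z1
  ft4 <- sc$ft4_mean + sc$ft4_sd * (sc$rho * z1 + sqrt(1 - sc$rho^2) * z2)
  tsh <- 10^ltsh
  # clean draws must sit inside the screening band and FT4 must be positive
  for (iter in 1:100) {
    bad <- tsh < rules$tsh_band[1] | tsh > rules$tsh_band[2] | ft4 <= 0
    if (!any(bad)) break
    nb <- sum(bad)
    z1b <- stats::rnorm(nb); z2b <- stats::rnorm(nb)
    tsh[bad] <- 10^(sc$tsh_log10_mu + sc$tsh_log10_sigma * z1b)
    ft4[bad] <- sc$ft4_mean + sc$ft4_sd * (sc$rho * z1b + sqrt(1 - sc$rho^2) * z2b)
  }
  tpoab <- stats::runif(n, 0.5, 0.9 * rules$tpoab_cutoff)
  tgab <- stats::runif(n, 2, 0.9 * rules$tgab_cutoff)
  block <- data.frame(id = NA_character_, sex = sex, age = as.integer(age),
                      tsh = tsh, ft4 = ft4, tpoab = tpoab, tgab = tgab,
                      stringsAsFactors = FALSE)
  for (f in .cohort_flags) block[[f]] <- FALSE
  block$medications <- ""
  if (sc$contamination_fraction > 0) {
    hit <- stats::runif(n) < sc$contamination_fraction
    if (any(hit)) {
      mech <- sample(names(mix), sum(hit), replace = TRUE, prob = mix)
      idx <- which(hit)
      for (k in seq_along(idx)) {
        j <- idx[k]
        switch(mech[k],
          high_tsh = { block$tsh[j] <- stats::runif(1, rules$tsh_band[2] * 1.005,
                                                    rules$tsh_band[2] * 2) },
          antibody_positive = { block$tpoab[j] <- stats::runif(1, rules$tpoab_cutoff,
                                                               10 * rules$tpoab_cutoff) },
          interfering_medication = {
            meds <- interfering_medications()
            block$medications[j] <- meds[sample.int(length(meds), 1L)]
          },
          recent_hospitalization = { block$hospitalized_6mo[j] <- TRUE },
          smoker = { block$smoker[j] <- TRUE })
      }
    }
  }
  block
}
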