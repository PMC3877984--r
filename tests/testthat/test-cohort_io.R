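# Cohort data model, delimited I/O, eligibility screening, stratification.

test_that("read/write round-trips a cohort field-by-field", {
  cohort <- clean_cohort(6)
  cohort$tsh[2] <- NA  # missing analyte must survive as missing, not zero
  cohort$medications[3] <- "amiodarone;vitamin c"
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(back, validate_cohort(cohort), ignore_attr = TRUE)
  expect_true(is.na(back$tsh[2]))

  # tab-delimited too
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(cohort, path2)
  expect_equal(read_cohort(path2), back, ignore_attr = TRUE)
})

test_that("generator output round-trips through text exactly at printed precision", {
  cohort <- generate_cohort(study_cohort_config(n_per_sex = 8, seed = 11,
                                                contamination_fraction = 0.3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(back$id, cohort$id)
  expect_equal(back$age, cohort$age)
  expect_equal(back$tsh, cohort$tsh, tolerance = 1e-12)
  expect_equal(back$medications, cohort$medications)
  expect_equal(back[.flags <- c("smoker", "pregnant")], cohort[.flags])
})

test_that("malformed cells and missing columns are reported precisely", {
  path <- withr::local_tempfile(fileext = ".csv")
  cohort <- clean_cohort(3)
  write_cohort(cohort, path)
  txt <- readLines(path)
  txt[3] <- sub("1.8", "abc", txt[3], fixed = TRUE)  # row 2 tsh
  writeLines(txt, path)
  expect_error(read_cohort(path), "tsh.*row 2")

  write.csv(cohort[, -3], path, row.names = FALSE)  # drop age
  expect_error(read_cohort(path), "schema.*age")
  expect_error(read_cohort(tempfile()), "not found")
})

test_that("validate_cohort enforces the subject-record invariants", {
  expect_error(validate_cohort(clean_record(age = 17L)), "age")
  expect_error(validate_cohort(clean_record(tsh = 0)), "positive")
  expect_error(validate_cohort(clean_record(sex = "male", pregnant = TRUE)),
               "pregnant")
  expect_silent(validate_cohort(clean_record()))
})

test_that("single-subject screening fires one reason per violated rule", {
  rules <- screening_rules()
  # outside the TSH screening band
  res <- screen_subject(clean_record(tsh = 10.5), rules)
  expect_false(res$eligible)
  expect_equal(res$reasons, "tsh_out_of_screen_band")
  expect_equal(screen_subject(clean_record(tsh = 0.05), rules)$reasons,
               "tsh_out_of_screen_band")
  # boundary: 10.0 is inside the band, antibody cutoffs are ">= is positive"
  expect_true(screen_subject(clean_record(tsh = 10.0), rules)$eligible)
  expect_equal(screen_subject(clean_record(tpoab = 40), rules)$reasons,
               "tpoab_positive")
  expect_equal(screen_subject(clean_record(tpoab = 34), rules)$reasons,
               "tpoab_positive")
  expect_true(screen_subject(clean_record(tpoab = 33.9), rules)$eligible)
  expect_equal(screen_subject(clean_record(tgab = 115), rules)$reasons,
               "tgab_positive")
  # flags and medications
  expect_equal(screen_subject(clean_record(smoker = TRUE), rules)$reasons,
               "flag_smoker")
  expect_equal(screen_subject(clean_record(medications = " Amiodarone "), rules)$reasons,
               "interfering_medication")
  expect_true(screen_subject(clean_record(medications = "vitamin c"), rules)$eligible)
  # exact-name matching: no substring false positives ("nitrate" is listed)
  expect_true(screen_subject(clean_record(medications = "glyceryl trinitrate spray"),
                             rules)$eligible)
  expect_equal(screen_subject(clean_record(medications = "nitrate"), rules)$reasons,
               "interfering_medication")
  # clean subject
  res <- screen_subject(clean_record(), rules)
  expect_true(res$eligible)
  expect_length(res$reasons, 0)
})

test_that("missing analytes yield insufficient_data, policy-dependent for antibodies", {
  rules <- screening_rules()
  expect_equal(screen_subject(clean_record(tsh = NA_real_), rules)$reasons,
               "insufficient_data")
  expect_equal(screen_subject(clean_record(tpoab = NA_real_), rules)$reasons,
               "insufficient_data")
  lax <- screening_rules(missing_antibody_policy = "ignore")
  expect_true(screen_subject(clean_record(tpoab = NA_real_), lax)$eligible)
})

test_that("cohort screening partitions exhaustively with per-reason counts", {
  cohort <- rbind(clean_cohort(7),
                  clean_record("X1", tsh = 12),
                  clean_record("X2", tpoab = 50),
                  clean_record("X3", smoker = TRUE))
  res <- screen_cohort(cohort)
  expect_equal(nrow(res$eligible) + nrow(res$excluded), nrow(cohort))
  expect_equal(nrow(res$eligible), 7)
  expect_equal(res$summary,
               c(flag_smoker = 1L, tpoab_positive = 1L, tsh_out_of_screen_band = 1L))
  # brute-force re-application of every rule agrees subject by subject
  for (i in seq_len(nrow(cohort))) {
    expect_equal(screen_subject(cohort[i, ], screening_rules())$eligible,
                 cohort$id[i] %in% res$eligible$id)
  }
  # multiplicity: one subject violating two rules counts under each reason
  cohort2 <- rbind(clean_cohort(2), clean_record("X9", tsh = 12, smoker = TRUE))
  res2 <- screen_cohort(cohort2)
  expect_equal(res2$n_excluded, 1L)
  expect_equal(sum(res2$summary), 2L)
  expect_error(screen_cohort(clean_cohort(0)), "nonempty")

  all_clean <- screen_cohort(clean_cohort(5))
  expect_equal(nrow(all_clean$eligible), 5)
  expect_length(all_clean$summary, 0)
})

test_that("screening is idempotent and monotone in the rule set", {
  cohort <- generate_cohort(study_cohort_config(n_per_sex = 20, seed = 5,
                                                contamination_fraction = 0.4))
  rules <- screening_rules()
  first <- screen_cohort(cohort, rules)
  again <- screen_cohort(first$eligible, rules)
  expect_equal(again$n_excluded, 0L)
  expect_equal(again$eligible$id, first$eligible$id)
  # dropping rules never shrinks the eligible set
  weaker <- screening_rules(tpoab_cutoff = Inf, tgab_cutoff = Inf,
                            medications = character(),
                            excluded_flags = "pregnant")
  relaxed <- screen_cohort(cohort, weaker)
  expect_true(all(first$eligible$id %in% relaxed$eligible$id))
})

test_that("contaminated generator output is screened at the configured rate", {
  cohort <- generate_cohort(study_cohort_config(n_per_sex = 100, seed = 9,
                                                contamination_fraction = 0.2))
  res <- screen_cohort(cohort)
  frac <- nrow(res$eligible) / nrow(cohort)
  # binomial 99.9% band around 0.8 at n = 1000
  expect_lt(abs(frac - 0.8), 3.3 * sqrt(0.8 * 0.2 / nrow(cohort)))
})

test_that("age strata assignment is total, unique and boundary-correct", {
  strata <- age_strata()
  expect_equal(as.character(assign_stratum(c(49, 50, 79, 80, 95))),
               c("20-49", "50-59", "70-79", ">=80", ">=80"))
  # every design-range age maps to exactly one stratum
  ages <- 20:100
  lab <- assign_stratum(ages)
  expect_false(anyNA(lab))
  counts <- sapply(ages, function(a) sum(a >= strata$lower & a <= strata$upper))
  expect_true(all(counts == 1))
  expect_error(assign_stratum(19), "out_of_design")
  expect_error(age_strata(lower = c(20, 55), upper = c(49, 60)), "contiguous")
})
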