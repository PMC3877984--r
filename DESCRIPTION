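Package: thyroRI
Title: Age-Specific Reference Intervals for Thyroid Function Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Establishes age-specific reference intervals (RI) for thyroid
    stimulating hormone (TSH) and free thyroxine (FT4) from screened adult
    cohorts: questionnaire/analyte eligibility screening, Dixon outlier
    removal, Kolmogorov-Smirnov (Lilliefors) distribution assessment,
    nonparametric 2.5th-97.5th percentile interval estimation, Harris-Boyd
    gender partitioning, rank-test driven merging of adjacent age bands,
    log10(TSH)-FT4 correlation with Fisher-z confidence intervals, and
    reclassification-impact comparison of competing RI sets. Includes a
    seeded synthetic-cohort generator emulating stratified log-normal TSH
    and Gaussian FT4 distributions so the whole pipeline runs without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
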