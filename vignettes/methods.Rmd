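---
title: "Methods: age-specific thyroid reference intervals in thyroRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-specific thyroid reference intervals in thyroRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyroRI)
```

## The model and its assumptions

thyroRI establishes reference intervals (RIs) for TSH (mU/L) and FT4
(ng/dL) in adults, allowing the interval to depend on age. The underlying
statistical model is deliberately minimal:

* **TSH** is treated as log10-normal within an age stratum. Raw TSH in
  reference populations is right-skewed and fails Kolmogorov–Smirnov
  normality in large samples, while log10 TSH passes; every analysis step
  that assumes a scale (outlier scanning, Harris–Boyd comparison, the
  correlation with FT4) therefore runs on log10 TSH. The reported interval
  bounds are nonparametric percentiles and do not depend on this
  distributional assumption — only the synthetic generator and the merge
  tests' efficiency do.
* **FT4** is treated as Gaussian within a stratum and analyzed raw.
* **Age enters as a stratified design**, not a regression: the recruitment
  strata are 20–49, 50–59, 60–69, 70–79 and ≥80 years (closed integer
  bands; the 80th birthday belongs to ≥80). The fitted object reports
  intervals for *merged groups* of contiguous strata.

A subject enters the reference population only after screening:
TSH inside (0.1, 10.0) mU/L, TPOAb < 34 IU/mL and TGAb < 115 IU/mL
(titres at or above the cutoff are positive — the assay defines negatives
as scoring *lower than* the cutoff), no thyroid or family-thyroid history,
goiter, smoking, recent hospitalization, pregnancy or iodine exposure, and
no medication on the packaged interference list. Matching against that
list is case-insensitive, whitespace-normalized and **exact-name**:
substring matching was rejected because entries such as "nitrate" would
falsely exclude unrelated drug names. A missing TSH or antibody titre
yields the reason code `insufficient_data` rather than a verdict — the
subject is set aside, not counted eligible, because inclusion required
demonstrably negative antibodies. This policy is configurable
(`missing_antibody_policy = "ignore"`), since how borderline or missing
titres were handled at recruitment is not documented.

## Estimation pipeline and numerical choices

1. **Distribution assessment.** `ks_normality()` computes the exact
   sup-distance between the ECDF and the normal fitted by sample mean/SD.
   Because the parameters are estimated, the raw KS null is
   anti-conservative; the default p-value is Lilliefors-corrected by Monte
   Carlo (`B = 1000` replicates, each re-standardized by its own
   mean/SD; `(1 + #{D_sim >= D}) / (B + 1)`). The uncorrected KS p remains
   available (`method = "ks"`) for comparison with software that ignores
   the estimation effect. The Monte Carlo consumes the RNG stream; the
   pipeline seeds it once per run so reports are reproducible.
2. **Outlier removal** precedes interval estimation and runs on the
   analysis scale (log10 for TSH, raw for FT4); whether the original
   analysis removed outliers before or after the log transform is
   unstated, and the log scale is the coherent choice given everything
   else runs there. The default rule is the CLSI-style range test: the
   extreme observation is discarded while its gap to the nearest neighbour
   exceeds one third of the current range, re-applied to either tail until
   nothing is flagged (the larger-ratio tail is removed first; zero range
   means no outliers). The classical Dixon-Q ratio test with two-tailed
   α = 0.05 critical values is available for n ≤ 30; the D/R rule is the
   default because typical RI strata (n = 120–480) are far beyond the Q
   table.
3. **Percentile convention.** `nonparametric_ri()` uses rank
   `r = p(n+1)` with linear interpolation between order statistics,
   clamped to [1, n] — the convention of nonparametric RI estimation
   guidelines, identical to `stats::quantile(type = 6)`. The same
   convention is used for descriptive quartiles, so Table-style summaries
   and interval bounds are mutually consistent. Bounds are reported
   rounded to 1 decimal (hormone RIs are printed at that precision);
   unrounded values are kept alongside. n ≥ 120 is the guideline minimum
   for nonparametric 95% limits; smaller series warn, below 20 is an
   error.
4. **Sex partitioning.** Harris–Boyd
   `z = (x̄₁ − x̄₂)/√(s₁²/n₁ + s₂²/n₂)` on the analysis scale, with the
   fixed critical value 3 (the rule the study states). The original
   sample-size-scaled criterion `3·√(n̄/120)` is available
   (`scaled = TRUE`); the two coincide at the design size of 120 per sex
   per stratum. Degenerate inputs are defined: equal means with zero SDs
   give z = 0 (no partition), differing means with zero SDs give infinite
   z (partition).
5. **Age-group merging.** `build_merge_plan()` walks the strata left to
   right, comparing the running merged block with the next stratum
   (Mann–Whitney asymptotic with tie and continuity correction for the
   rank family; pooled-variance Student t for the Gaussian family) and
   absorbing it when non-significant at α = 0.05. The original analysis
   reports only the two adjacent pairwise tests it ran, each at an
   unadjusted p > 0.05, so the default applies **no multiplicity
   adjustment** across the k − 1 adjacent decisions; Bonferroni is
   available (`adjust = "bonferroni"`). This "non-significant ⇒ merge"
   logic is a known statistical weakness (absence of evidence), faithfully
   reproduced; an equivalence-testing alternative is out of scope.
6. **Correlation.** Pearson r of log10 TSH vs FT4 per stratum, two-tailed
   p from the t transform, CI by Fisher's z with `n − 3` denominator.
   `r_squared` is asserted equal to `r²` to machine tolerance — published
   correlation tables occasionally violate this internal consistency, and
   the implementation refuses to reproduce such inconsistencies.
7. **Reclassification.** Values equal to an interval bound are *within*
   (RIs are inclusive; the source table never states its convention).
   Percentages are computed unrounded; the printed-table view rounds to
   1 decimal and recomputes the difference columns from the rounded
   percentages, since that is how the published comparison table's
   differences reconcile. Both views are exposed.

## The synthetic generator: what it emulates, and what not

`generate_cohort()` draws, per stratum × sex cell, (log10 TSH, FT4) from a
bivariate normal via a 2×2 Cholesky factor, exponentiating the TSH
coordinate — so the correlation is imposed between **log10 TSH** and FT4,
matching the analysis scale. `study_cohort_config()` fixes the defaults to
the published world: per-decade log10-σ from the printed 25th/75th TSH
percentiles (σ = (log10 q75 − log10 q25)/(2·0.6745)); per-decade medians
from the merged-group assumed values (1.5, 1.5, 1.7, 1.7, 2.0 mU/L) because
the per-decade median rows are ambiguously printed while the
quartile-midpoint alternative would contradict the study's own
non-significant 20–49 vs 50–59 comparison; FT4 means/SDs 1.2 ± 0.3 (under
60) and 1.1 ± 0.2 (60+); per-stratum correlations −0.46, −0.39, −0.47,
−0.49, −0.40; 120 subjects per sex per stratum. Ages are uniform over each
stratum's integer range, capped at 95 in the open-ended stratum
(configurable). Substream seeds derive deterministically from
(seed, stratum, sex), so identical configurations give byte-identical
cohorts and per-cell draws do not interact.

Clean subjects are constructed to pass screening: antibody titres are drawn
uniformly below 90% of the cutoffs, flags are false, and TSH draws landing
outside the screening band — a ≤ 0.6% tail event under the widest
calibrations — are redrawn. That clip keeps the "zero contamination ⇒ all
eligible" property but truncates the distribution's extreme tail, so
**bound-recovery experiments**, whose premise is that the generating
distribution's true 2.5th/97.5th percentiles equal the calibration, pass
wide-band rules to disable it. Contaminated subjects (a Bernoulli fraction)
receive exactly one exclusion mechanism drawn from a configurable mix —
high TSH, positive TPOAb, an interfering medication, recent
hospitalization, or smoking; mechanisms are mutually exclusive per subject
because multiplicity adds nothing testable.

The generator does **not** emulate: assay measurement noise calibrated to
the manufacturer's CV table, heavier-than-log-normal TSH tails, antibody
titre structure beyond negative/positive, longitudinal repeat testing, or
any dependence of eligibility on unmodelled laboratory panels. A green
recovery test therefore establishes that the estimators invert the stated
world, not that the published cohort's raw values are reproduced — the
study's own per-stratum tables derive from its unreleased data and are
targeted only through calibrated recovery.

## Tolerances and known limits worth knowing

* The Mann–Whitney normal approximation (with continuity correction)
  agrees with exhaustive-enumeration exact p-values to within 0.02 once
  both groups have ≥ 5 observations (verified exhaustively for total
  n ≤ 12); its worst deviation below that is 0.0375 at 3 + 3. The exact
  mode enumerates all labelings and is limited to total n ≤ 12.
* The interpolated-rank percentile estimator is mean-biased upward in a
  log-normal right tail: for the ≥80 calibration (true 97.5th = 6.7 mU/L)
  at n = 240 the expected recovered upper bound is ≈ 6.88 mU/L. This is a
  property of the estimator class, shrinking roughly like 1/n; recovery
  checks at ±0.2 mU/L operate at the edge of it.
* Dunn pairwise z tests Bonferroni-adjust over the pairs tested in the
  call; the omnibus Kruskal–Wallis is enforced as a warning, not a gate.
* The FT4 comparison family is one-way (Student t / one-way ANOVA); the
  original description names a two-way design while describing one-factor
  comparisons, and the two-factor intent was not guessed.
* `simulate()` on a fitted TSH model draws from the log10-normal whose
  central interval equals the fitted unrounded bounds — a parametric
  idealization of a nonparametric fit.

## A small demonstration

```{r demo}
cohort <- generate_cohort(study_cohort_config(n_per_sex = 60, seed = 7))
fit <- ri_fit(tsh ~ sex + age, cohort)
fit
coef(fit)
```
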