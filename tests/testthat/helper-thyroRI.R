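# Shared fixtures, built in code.

# One clean, mid-range subject record; override fields via ...
clean_record <- function(id = "S1", sex = "female", age = 45L, ...) {
  rec <- data.frame(id = id, sex = sex, age = age,
                    tsh = 1.8, ft4 = 1.2, tpoab = 10, tgab = 50,
                    thyroid_history = FALSE, family_thyroid_history = FALSE,
                    goiter = FALSE, smoker = FALSE, hospitalized_6mo = FALSE,
                    pregnant = FALSE, iodine_exposure_6mo = FALSE,
                    medications = "", stringsAsFactors = FALSE)
  dots <- list(...)
  for (nm in names(dots)) rec[[nm]] <- dots[[nm]]
  rec
}

# n clean records spread over the default strata
clean_cohort <- function(n = 10L, ages = NULL) {
  if (is.null(ages)) ages <- 20 + (seq_len(n) * 7) %% 70
  do.call(rbind, lapply(seq_len(n), function(i)
    clean_record(id = sprintf("S%03d", i),
                 sex = c("female", "male")[1 + i %% 2], age = ages[i])))
}

# Pair (x, y) of length n whose sample Pearson correlation is exactly r.
make_exact_cor <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- scale(rnorm(n))[, 1]
  e <- residuals(lm(rnorm(n) ~ x))
  e <- scale(e)[, 1]
  list(x = x, y = r * x + sqrt(1 - r^2) * e)
}

# Exact two-tailed Mann-Whitney p by full enumeration (independent oracle,
# kept separate from the package's own exact mode).
oracle_mw_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(nx + ny, nx)
  us <- colSums(matrix(r[idx], nrow = nx)) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(u - mu) - 1e-9)
}
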