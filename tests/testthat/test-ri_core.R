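# Scale transforms, normality assessment, Dixon scan, RI estimation,
# descriptive summaries.

test_that("log10 transform is exact, invertible and order-preserving", {
  s <- analyte_series(c(1, 10, 100), "TSH")
  t <- log10_transform(s)
  expect_equal(as.numeric(t), c(0, 1, 2))
  expect_equal(attr(t, "scale"), "log10")
  expect_equal(as.numeric(inv_log10_transform(t)), c(1, 10, 100), tolerance = 1e-12)

  set.seed(4)
  x <- rlnorm(200)
  expect_equal(order(log10_transform(x)), order(x))
  expect_equal(inv_log10_transform(log10_transform(x)), x, tolerance = 1e-12)
  expect_error(log10_transform(c(1, -2, 3)), "index 2")
  expect_error(log10_transform(analyte_series(c(1, 2), "TSH", scale = "log10")),
               "already")
})

test_that("KS statistic equals the brute-force ECDF supremum", {
  # brute-force sup over the 2n candidate points, for several small series
  brute <- function(x) {
    m <- mean(x); s <- sd(x); xs <- sort(x); n <- length(x)
    cand <- c()
    for (i in seq_len(n)) {
      f <- pnorm((xs[i] - m) / s)
      cand <- c(cand, abs(i / n - f), abs((i - 1) / n - f))
    }
    max(cand)
  }
  set.seed(9)
  for (n in c(5, 8, 17)) {
    x <- rnorm(n)
    expect_equal(ks_normality(x * 10 + 2, method = "ks")$statistic
                 , brute(x * 10 + 2), tolerance = 1e-12)
  }
  # and against the stock KS implementation on the fitted normal
  x <- rnorm(50)
  expect_equal(ks_normality(x, method = "ks")$statistic,
               unname(ks.test(x, "pnorm", mean(x), sd(x))$statistic),
               tolerance = 1e-12)
})

test_that("Lilliefors decision separates normal from log-normal data", {
  set.seed(101)
  x <- rnorm(1e4, 50, 3)
  res <- ks_normality(x, B = 400)
  expect_true(res$normal_at_alpha)
  expect_true(res$p_value > res$alpha)

  y <- rlnorm(1e4, 0, 0.3)  # sigma(log10) ~ 0.13 but n large: clearly skewed
  set.seed(101)
  expect_false(ks_normality(y, B = 400)$normal_at_alpha)
  set.seed(101)
  expect_true(ks_normality(log10(y), B = 400)$normal_at_alpha)
  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(rnorm(4)), "at least 5")
})

test_that("Dixon D/R scan flags gross outliers and spares even spacing", {
  rep1 <- dixon_outliers(c(1, 2, 3, 4, 5, 100))
  expect_equal(rep1$flagged_indices, 6L)
  expect_equal(rep1$statistic_per_flag, 95 / 99, tolerance = 1e-12)

  rep2 <- dixon_outliers(1:10)
  expect_length(rep2$flagged_indices, 0)

  # all equal: zero range handled as no outliers
  expect_length(dixon_outliers(rep(3.3, 8))$flagged_indices, 0)

  # iterative: two stacked high outliers both removed
  rep3 <- dixon_outliers(c(1, 1.1, 1.2, 1.3, 1.4, 1.5, 8, 60))
  expect_equal(sort(rep3$flagged_indices), c(7L, 8L))

  # low-tail outlier
  rep4 <- dixon_outliers(c(-50, 10, 11, 12, 13, 14))
  expect_equal(rep4$flagged_indices, 1L)
  expect_error(dixon_outliers(c(1, 2)), "at least 3")
})

test_that("Dixon flags are invariant under positive affine rescaling", {
  set.seed(12)
  for (i in 1:10) {
    x <- c(rnorm(30), rnorm(2, 6))
    a <- dixon_outliers(x)
    b <- dixon_outliers(3.7 * x + 11)
    expect_equal(a$flagged_indices, b$flagged_indices)
    expect_equal(a$statistic_per_flag, b$statistic_per_flag, tolerance = 1e-9)
  }
})

test_that("classical Dixon-Q flags an obvious outlier at small n and not clean data", {
  expect_equal(dixon_outliers(c(1.1, 1.2, 1.3, 1.15, 9), method = "dixon_q")$flagged_indices,
               5L)
  expect_length(dixon_outliers(c(1.1, 1.2, 1.3, 1.15, 1.25),
                               method = "dixon_q")$flagged_indices, 0)
  expect_error(dixon_outliers(rnorm(40), method = "dixon_q"), "n <= 30")
  expect_error(dixon_outliers(rnorm(10), method = "dixon_q", alpha = 0.01), "0.05")
})

test_that("nonparametric RI follows the rank = p(n+1) convention", {
  ri <- suppressWarnings(nonparametric_ri(1:119, rounding = 6))
  expect_equal(c(ri$lower_raw, ri$upper_raw), c(3, 117))
  expect_equal(ri$n_used, 119)
  expect_equal(ri$method, "nonparametric_rank")

  # brute-force oracle: sort + interpolate at rank p(n+1), clamped
  brute_q <- function(x, p) {
    xs <- sort(x); n <- length(x)
    r <- max(1, min(n, p * (n + 1)))
    lo <- floor(r); hi <- ceiling(r)
    xs[lo] + (r - lo) * (xs[hi] - xs[lo])
  }
  set.seed(21)
  for (i in 1:10) {
    x <- rlnorm(sample(25:400, 1), 0.2, 0.3)
    ri <- suppressWarnings(nonparametric_ri(x, rounding = 8))
    expect_equal(ri$lower_raw, brute_q(x, 0.025), tolerance = 1e-10)
    expect_equal(ri$upper_raw, brute_q(x, 0.975), tolerance = 1e-10)
  }

  # degenerate constant series
  ri <- suppressWarnings(nonparametric_ri(rep(2.5, 30)))
  expect_equal(c(ri$lower, ri$upper), c(2.5, 2.5))

  expect_error(nonparametric_ri(1:10), "at least 20")
  expect_error(suppressWarnings(nonparametric_ri(1:30, coverage = 1.2)), "coverage")
  expect_warning(nonparametric_ri(1:60), "120")
})

test_that("RI is monotone in coverage and equivariant under log10", {
  set.seed(31)
  x <- rlnorm(300, 0.3, 0.4)
  r90 <- suppressWarnings(nonparametric_ri(x, coverage = 0.90, rounding = 8))
  r95 <- suppressWarnings(nonparametric_ri(x, coverage = 0.95, rounding = 8))
  r99 <- suppressWarnings(nonparametric_ri(x, coverage = 0.99, rounding = 8))
  expect_true(r90$lower_raw >= r95$lower_raw && r95$lower_raw >= r99$lower_raw)
  expect_true(r90$upper_raw <= r95$upper_raw && r95$upper_raw <= r99$upper_raw)

  # log-scale estimation then back-transform agrees with raw-scale
  # estimation (to interpolation error, small relative to the bounds)
  rlog <- suppressWarnings(nonparametric_ri(log10(x), rounding = 8))
  expect_equal(10^rlog$lower_raw, r95$lower_raw, tolerance = 0.01)
  expect_equal(10^rlog$upper_raw, r95$upper_raw, tolerance = 0.01)
})

test_that("large-sample RI converges to the analytic quantiles", {
  pars <- calibrate_lognormal_from_bounds(0.4, 5.8)
  set.seed(41)
  x <- 10^rnorm(1e6, pars[["tsh_log10_mu"]], pars[["tsh_log10_sigma"]])
  ri <- nonparametric_ri(x, rounding = 8)
  expect_equal(ri$lower_raw / 0.4, 1, tolerance = 0.005)
  expect_equal(ri$upper_raw / 5.8, 1, tolerance = 0.005)
})

test_that("descriptive summary matches the shared rank convention", {
  d <- describe_series(c(1, 2, 3, 4, 5))
  expect_equal(d$median, 3)
  expect_equal(d$q25, 1.5)  # rank 0.25 * 6 = 1.5, interpolated
  expect_equal(d$q75, 4.5)
  expect_equal(d$mean, d$median)  # symmetric series

  set.seed(51)
  x <- rnorm(5000, 10, 2)
  d <- describe_series(x)
  expect_equal(d$median, 10, tolerance = 0.1)
  expect_equal(d$sd, 2, tolerance = 0.1)
  # median CI: contains the median, conservative coverage on repeated draws
  expect_true(d$median_ci[["lower"]] <= d$median && d$median <= d$median_ci[["upper"]])
  cover <- mean(vapply(1:200, function(i) {
    ci <- describe_series(rnorm(61))$median_ci
    ci[["lower"]] <= 0 && 0 <= ci[["upper"]]
  }, TRUE))
  expect_gte(cover, 0.93)
})
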