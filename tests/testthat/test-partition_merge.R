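# Harris-Boyd partitioning, rank and Gaussian comparisons, merge plans.

test_that("Harris-Boyd z follows the pooled-SE formula and the critical rule", {
  a <- list(label = "female", n = 120, mean = 1.2, sd = 0.24)
  b <- list(label = "male", n = 120, mean = 1.3, sd = 0.25)
  d <- harris_boyd_z(a, b)
  expect_equal(d$z, -0.1 / sqrt((0.24^2 + 0.25^2) / 120), tolerance = 1e-12)
  expect_equal(abs(round(d$z, 3)), 3.161)
  expect_true(d$partition_required)

  # identical stats
  d0 <- harris_boyd_z(a, a)
  expect_equal(d0$z, 0)
  expect_false(d0$partition_required)

  # strictly below the critical value: no partition (z < 3 rule)
  b29 <- list(label = "male", n = 120, mean = a$mean + 2.9 * sqrt(2 * a$sd^2 / 120),
              sd = 0.24)
  expect_false(harris_boyd_z(b29, a)$partition_required)
  # at the critical value: partition
  b30 <- list(label = "male", n = 120, mean = a$mean + 3 * sqrt(2 * a$sd^2 / 120),
              sd = 0.24)
  expect_true(harris_boyd_z(b30, a)$partition_required)

  # degenerate variances
  z1 <- harris_boyd_z(list(n = 5, mean = 1, sd = 0), list(n = 5, mean = 1, sd = 0))
  expect_equal(z1$z, 0)
  z2 <- harris_boyd_z(list(n = 5, mean = 2, sd = 0), list(n = 5, mean = 1, sd = 0))
  expect_true(is.infinite(z2$z) && z2$partition_required)
})

test_that("Harris-Boyd z is antisymmetric and scale-invariant", {
  set.seed(3)
  for (i in 1:10) {
    a <- stratum_stats(rnorm(50, 1, 0.3), "a")
    b <- stratum_stats(rnorm(70, 1.1, 0.25), "b")
    expect_equal(harris_boyd_z(a, b)$z, -harris_boyd_z(b, a)$z, tolerance = 1e-12)
    sa <- a; sb <- b
    sa$mean <- 5 * a$mean + 2; sa$sd <- 5 * a$sd
    sb$mean <- 5 * b$mean + 2; sb$sd <- 5 * b$sd
    expect_equal(harris_boyd_z(sa, sb)$z, harris_boyd_z(a, b)$z, tolerance = 1e-9)
  }
  # scaled critical value coincides with the fixed one at n = 120 per group
  a <- list(n = 120, mean = 1, sd = 0.2); b <- list(n = 120, mean = 1.1, sd = 0.2)
  expect_equal(harris_boyd_z(a, b, scaled = TRUE)$critical,
               harris_boyd_z(a, b)$critical)
})

test_that("Mann-Whitney exact mode enumerates the labelings", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)  # 2/20 labelings as extreme

  # identical samples: p = 1
  expect_equal(mann_whitney(c(2, 4, 9), c(2, 4, 9), mode = "exact")$p_value, 1)

  # agrees with the stock exact U test when there are no ties
  set.seed(14)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(6, 1)
    expect_equal(mann_whitney(x, y, mode = "exact")$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  expect_error(mann_whitney(numeric(), 1:3), "nonempty")
  expect_error(mann_whitney(1:10, 1:10, mode = "exact"), "n <= 12")
})

test_that("asymptotic Mann-Whitney approximates the exact oracle at n = 6 + 6", {
  set.seed(15)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(6, runif(1, 0, 2))
    pe <- oracle_mw_exact(x, y)
    pa <- mann_whitney(x, y, mode = "asymptotic")$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("Kruskal-Wallis H matches hand rank arithmetic and a permutation oracle", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  res <- kruskal_wallis(g)
  # rank sums 3, 7, 11: H = 12/(6*7) * (9 + 49 + 121)/2 - 3*7 = 32/7
  expect_equal(res$statistic, 32 / 7, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, pchisq(32 / 7, 2, lower.tail = FALSE), tolerance = 1e-12)

  # exhaustive permutation p over all 6!/(2!2!2!) assignments
  perm_h <- apply(combn(6, 2), 2, function(i) {
    rest <- setdiff(1:6, i)
    apply(combn(rest, 2), 2, function(j)
      kruskal_wallis(list(i, j, setdiff(rest, j)))$statistic)
  })
  p_perm <- mean(perm_h >= res$statistic - 1e-9)
  expect_lt(abs(p_perm - res$p_value), 0.05)

  expect_error(kruskal_wallis(list(1:3, 4:6)), "mann_whitney")
  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1), c(1, 1))), "tied")
})

test_that("Dunn pairwise comparisons: Bonferroni arithmetic and detection", {
  set.seed(16)
  g <- list(a = rnorm(40), b = rnorm(40), c = rnorm(40, 3))
  res <- dunn_pairwise(g)
  expect_length(res, 3)
  for (cmp in res) {
    expect_true(cmp$adjusted)
    expect_equal(cmp$p_value, min(1, 3 * cmp$p_unadjusted), tolerance = 1e-12)
    expect_gte(cmp$p_value, cmp$p_unadjusted)
  }
  lab <- vapply(res, function(cmp) paste(cmp$labels, collapse = "-"), "")
  p <- vapply(res, `[[`, 0, "p_value")
  expect_gt(p[lab == "a-b"], 0.05)       # identical pair not flagged
  expect_lt(p[lab == "a-c"], 0.05)       # shifted pair flagged
  expect_lt(p[lab == "b-c"], 0.05)

  # warns when the omnibus test is not significant
  g0 <- list(rnorm(10), rnorm(10), rnorm(10))
  expect_warning(dunn_pairwise(g0), "omnibus|exploratory")
})

test_that("Gaussian comparisons: Student t by hand, F = t^2 identity", {
  res <- gaussian_compare(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(res$statistic, -1 / sqrt(2 / 3), tolerance = 1e-12)  # -1.2247
  expect_equal(round(res$statistic, 4), -1.2247)
  expect_equal(res$df, 4)
  expect_equal(res$test, "student_t")

  same <- gaussian_compare(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # three groups route through one-way ANOVA
  set.seed(17)
  res3 <- gaussian_compare(list(rnorm(10), rnorm(10), rnorm(10, 3)))
  expect_equal(res3$test, "anova")
  expect_lt(res3$p_value, 0.01)
})

test_that("one-way ANOVA reduces to t^2 for two groups", {
  set.seed(18)
  x <- rnorm(12); y <- rnorm(15, 0.4)
  tt <- gaussian_compare(list(x, y))
  an <- anova(lm(c(x, y) ~ factor(rep(1:2, c(12, 15)))))
  expect_equal(an[["F value"]][1], tt$statistic^2, tolerance = 1e-10)
  expect_equal(an[["Pr(>F)"]][1], tt$p_value, tolerance = 1e-10)
  expect_error(gaussian_compare(list(c(1, 1), c(2, 2))), "zero within-group")
})

test_that("merge plans reproduce forced patterns and are exhaustive/contiguous", {
  set.seed(19)
  n <- 60
  # ns, sig, ns, sig -> {1+2}, {3+4}, {5}
  s <- list("20-49" = rnorm(n, 0), "50-59" = rnorm(n, 0),
            "60-69" = rnorm(n, 2), "70-79" = rnorm(n, 2),
            ">=80" = rnorm(n, 4))
  plan <- build_merge_plan(s, test_family = "rank")
  expect_equal(plan$group_labels, c("20-59", "60-79", ">=80"))
  expect_equal(unlist(plan$groups), names(s))  # exhaustive, in order

  # all separated -> singletons; all identical -> one group
  s_far <- lapply(0:4 * 10, function(m) rnorm(n, m))
  names(s_far) <- names(s)
  expect_length(build_merge_plan(s_far)$groups, 5)
  s_same <- lapply(1:5, function(i) rnorm(n))
  names(s_same) <- names(s)
  expect_length(build_merge_plan(s_same, alpha = 0.001)$groups, 1)

  # gaussian family works and reports t tests
  plan_g <- build_merge_plan(s, test_family = "gaussian")
  expect_equal(plan_g$group_labels, c("20-59", "60-79", ">=80"))
  expect_true(all(plan_g$comparisons$test == "student_t"))

  # bonferroni adjustment never splits more than unadjusted
  plan_b <- build_merge_plan(s, adjust = "bonferroni")
  expect_lte(length(plan_b$groups), length(plan$groups))
})

test_that("rank-family merge plans are invariant to monotone transforms", {
  set.seed(20)
  s <- list("20-49" = rlnorm(50, 0, 0.3), "50-59" = rlnorm(50, 0.1, 0.3),
            "60-69" = rlnorm(50, 0.6, 0.3), "70-79" = rlnorm(50, 0.6, 0.3),
            ">=80" = rlnorm(50, 1.2, 0.3))
  p1 <- build_merge_plan(s, test_family = "rank")
  p2 <- build_merge_plan(lapply(s, log10), test_family = "rank")
  p3 <- build_merge_plan(lapply(s, function(v) v^3), test_family = "rank")
  expect_equal(p1$groups, p2$groups)
  expect_equal(p1$comparisons$p_value, p2$comparisons$p_value, tolerance = 1e-12)
  expect_equal(p1$groups, p3$groups)
})

test_that("merged group labels and bounds derive from the strata", {
  set.seed(22)
  s <- list("20-49" = rnorm(40), "50-59" = rnorm(40),
            "60-69" = rnorm(40, 3), "70-79" = rnorm(40, 3), ">=80" = rnorm(40, 3))
  plan <- build_merge_plan(s)
  b <- merge_plan_bounds(plan)
  expect_equal(b$label, plan$group_labels)
  expect_equal(b$lower[1], 20)
  expect_true(is.infinite(b$upper[nrow(b)]))
})
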