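# Partitioning statistics: Harris-Boyd z for subgroup RIs, and the rank
# and Gaussian group comparisons used to justify merging age bands.

#' Summary statistics of one stratum
#'
#' @param x numeric vector on the analysis scale (log10 for TSH, raw for
#'   FT4).
#' @param label stratum label.
#' @param raw optional raw-scale values for the median (defaults to `x`).
#' @return object of class `stratum_stats`: `label`, `n`, `mean`, `sd`
#'   (analysis scale), `median` (raw scale).
#' @export
stratum_stats <- function(x, label = NULL, raw = x) {
  x <- as.numeric(x[!is.na(x)])
  if (length(x) < 2L) stop("need n >= 2 per stratum")
  out <- list(label = label, n = length(x), mean = mean(x), sd = stats::sd(x),
              median = stats::median(as.numeric(raw), na.rm = TRUE))
  class(out) <- "stratum_stats"
  out
}

#' Harris-Boyd partitioning criterion
#'
#' Decides whether two subgroups (typically the sexes) need separate
#' reference intervals:
#' `z = (mean_a - mean_b) / sqrt(sd_a^2/n_a + sd_b^2/n_b)`.
#' Partitioning is required when `|z|` reaches the critical value; the
#' study's rule fixes it at 3. The original sample-size-scaled criterion
#' `z* = 3 * sqrt(((n_a + n_b)/2) / 120)` (identical at the design size
#' of 120 per group) is available via `scaled = TRUE`.
#'
#' @param a,b [stratum_stats()] objects (or lists with `n`, `mean`, `sd`).
#' @param critical critical value (default 3).
#' @param scaled use the sample-size-scaled critical value.
#' @return object of class `partition_decision`: `pair`, `z`, `critical`,
#'   `partition_required` (`|z| >= critical`).
#' @examples
#' a <- list(label = "female", n = 120, mean = 1.2, sd = 0.24)
#' b <- list(label = "male",   n = 120, mean = 1.3, sd = 0.25)
#' harris_boyd_z(a, b)
#' @export
harris_boyd_z <- function(a, b, critical = 3, scaled = FALSE) {
  stopifnot(a$n >= 2, b$n >= 2)
  se <- sqrt(a$sd^2 / a$n + b$sd^2 / b$n)
  z <- if (se == 0) {
    if (a$mean == b$mean) 0 else sign(a$mean - b$mean) * Inf
  } else (a$mean - b$mean) / se
  crit <- if (scaled) critical * sqrt(((a$n + b$n) / 2) / 120) else critical
  out <- list(pair = c(a$label, b$label), z = z, critical = crit,
              partition_required = abs(z) >= crit)
  class(out) <- "partition_decision"
  out
}

#' @export
print.partition_decision <- function(x, ...) {
  cat(sprintf("Harris-Boyd: %s vs %s, z = %.3f (critical %.3f) -> %s\n",
              x$pair[1], x$pair[2], x$z, x$critical,
              if (x$partition_required) "partition" else "common RI"))
  invisible(x)
}

.comparison <- function(test, statistic, p_value, labels, adjusted = FALSE, ...) {
  out <- c(list(test = test, statistic = unname(statistic),
                p_value = unname(p_value), labels = labels,
                adjusted = adjusted), list(...))
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s [%s]: statistic = %.4g, p = %.4g%s\n", x$test,
              paste(x$labels, collapse = " vs "), x$statistic, x$p_value,
              if (isTRUE(x$adjusted)) " (adjusted)" else ""))
  invisible(x)
}

#' Two-tailed Mann-Whitney test
#'
#' Exact mode enumerates all `choose(n_x + n_y, n_x)` group labelings of
#' the pooled sample (feasible for total n <= 12) and computes
#' `P(|U - E[U]| >= |u - E[U]|)`; asymptotic mode is the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y nonempty numeric samples.
#' @param mode `"auto"` (exact when total n <= 12), `"exact"`, or
#'   `"asymptotic"`.
#' @param labels group labels.
#' @return a `group_comparison` with `statistic` = U for the first sample.
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "asymptotic"),
                         labels = c("x", "y")) {
  mode <- match.arg(mode)
  x <- as.numeric(x[!is.na(x)]); y <- as.numeric(y[!is.na(y)])
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) stop("both samples must be nonempty")
  if (mode == "auto") mode <- if (nx + ny <= 12L) "exact" else "asymptotic"
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (mode == "exact") {
    if (nx + ny > 12L) stop("exact enumeration limited to total n <= 12")
    idx <- utils::combn(nx + ny, nx)
    us <- colSums(matrix(r[idx], nrow = nx)) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
  } else {
    p <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE)$p.value)
  }
  .comparison("mann_whitney", u, p, labels, mode = mode)
}

#' Kruskal-Wallis rank test
#'
#' H statistic with tie correction, p from the chi-square approximation
#' with k - 1 degrees of freedom.
#'
#' @param groups list of >= 3 nonempty numeric vectors.
#' @param labels group labels.
#' @return a `group_comparison` (with `df`).
#' @export
kruskal_wallis <- function(groups, labels = names(groups)) {
  if (!is.list(groups) || length(groups) < 3L)
    stop("need >= 3 groups (use mann_whitney for 2)")
  if (any(vapply(groups, length, 0L) == 0L)) stop("all groups must be nonempty")
  if (is.null(labels)) labels <- paste0("g", seq_along(groups))
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1L)
    stop("degenerate data: all observations tied")
  kt <- stats::kruskal.test(groups)
  .comparison("kruskal_wallis", kt$statistic, kt$p.value, labels,
              df = unname(kt$parameter))
}

#' Dunn pairwise comparisons after Kruskal-Wallis
#'
#' z statistics on pooled mid-ranks with the tie-corrected variance
#' `(N(N+1)/12 - T/(12(N-1))) * (1/n_i + 1/n_j)` where
#' `T = sum(t^3 - t)` over tie groups; two-sided p-values are
#' Bonferroni-adjusted over the tested pairs.
#'
#' @param groups list of >= 3 nonempty numeric vectors.
#' @param labels group labels.
#' @param alpha level used only to warn when the omnibus Kruskal-Wallis
#'   is not significant.
#' @param pairs 2-column integer matrix of group index pairs to test;
#'   default all pairs.
#' @return list of `group_comparison` objects (with `p_unadjusted`).
#' @export
dunn_pairwise <- function(groups, labels = names(groups), alpha = 0.05,
                          pairs = NULL) {
  kw <- kruskal_wallis(groups, labels)
  if (kw$p_value >= alpha)
    warning("omnibus Kruskal-Wallis not significant at alpha = ", alpha,
            "; pairwise comparisons are exploratory")
  if (is.null(labels)) labels <- paste0("g", seq_along(groups))
  if (is.null(pairs)) pairs <- t(utils::combn(length(groups), 2L))
  n <- vapply(groups, length, 0L)
  N <- sum(n)
  r <- rank(unlist(groups))
  grp <- rep(seq_along(groups), n)
  rbar <- tapply(r, grp, mean)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  m <- nrow(pairs)
  out <- vector("list", m)
  for (k in seq_len(m)) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    z <- (rbar[[i]] - rbar[[j]]) / sqrt(v0 * (1 / n[i] + 1 / n[j]))
    p_raw <- 2 * stats::pnorm(-abs(z))
    out[[k]] <- .comparison("dunn", z, min(1, m * p_raw),
                            c(labels[i], labels[j]), adjusted = TRUE,
                            p_unadjusted = p_raw, m = m)
  }
  out
}

#' Gaussian group comparison
#'
#' Two groups: two-sided Student t with pooled variance. More than two:
#' one-way ANOVA F. (The FT4 analysis names a two-way design but
#' describes one-factor comparisons; the single-factor form is
#' implemented.)
#'
#' @param groups list of numeric vectors, each n >= 2.
#' @param labels group labels.
#' @return a `group_comparison` (with `df`).
#' @export
gaussian_compare <- function(groups, labels = names(groups)) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, 0L) < 2L)) stop("each group needs n >= 2")
  if (all(vapply(groups, function(g) stats::var(g) == 0, TRUE)))
    stop("zero within-group variance everywhere")
  if (is.null(labels)) labels <- paste0("g", seq_along(groups))
  if (length(groups) == 2L) {
    tt <- stats::t.test(groups[[1]], groups[[2]], var.equal = TRUE)
    .comparison("student_t", tt$statistic, tt$p.value, labels,
                df = unname(tt$parameter))
  } else {
    y <- unlist(groups)
    g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
    an <- stats::anova(stats::lm(y ~ g))
    .comparison("anova", an[["F value"]][1], an[["Pr(>F)"]][1], labels,
                df = an$Df[1:2])
  }
}
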