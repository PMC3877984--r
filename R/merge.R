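# Merging adjacent age strata into shared-RI groups.
#
# The study tested adjacent age bands pairwise and merged those with no
# significant difference (p > 0.05), arriving at three TSH groups: 20-59,
# 60-79 and >=80. The generalization here is greedy and left-to-right:
# the running merged block is compared with the next stratum and absorbed
# into it when the comparison is non-significant. Comparisons are
# two-group tests (Mann-Whitney for the rank family, Student t for the
# Gaussian family); the study reports per-pair unadjusted p-values, so no
# multiplicity adjustment is applied by default (Bonferroni over the
# k - 1 adjacent comparisons is available).

#' Build a merge plan over ordered age strata
#'
#' @param strata_series named list of numeric vectors (analysis scale),
#'   one per stratum, in age order.
#' @param test_family `"rank"` (Mann-Whitney; appropriate for TSH) or
#'   `"gaussian"` (Student t; appropriate for FT4).
#' @param alpha significance level for splitting (default 0.05).
#' @param adjust `"none"` (default; mirrors the study's per-pair
#'   decisions) or `"bonferroni"` over the k - 1 adjacent comparisons.
#' @return object of class `merge_plan`: list with `strata` (input
#'   labels), `groups` (list of label vectors, contiguous and exhaustive),
#'   `group_labels` (compact labels such as "20-59"), `comparisons`
#'   (data.frame of each adjacent test), `alpha`, `test_family`.
#' @examples
#' set.seed(1)
#' s <- list("20-49" = rnorm(50), "50-59" = rnorm(50), "60-69" = rnorm(50, 2))
#' build_merge_plan(s)
#' @export
build_merge_plan <- function(strata_series,
                             test_family = c("rank", "gaussian"),
                             alpha = 0.05,
                             adjust = c("none", "bonferroni")) {
  test_family <- match.arg(test_family)
  adjust <- match.arg(adjust)
  k <- length(strata_series)
  if (k < 2L) stop("need at least 2 strata")
  labs <- names(strata_series)
  if (is.null(labs)) labs <- paste0("s", seq_len(k))
  m_adj <- if (adjust == "bonferroni") k - 1L else 1L
  groups <- list(1L)
  cmp <- data.frame(block = character(), stratum = character(),
                    test = character(), statistic = numeric(),
                    p_value = numeric(), p_adjusted = numeric(),
                    significant = logical(), stringsAsFactors = FALSE)
  for (j in 2L:k) {
    cur <- groups[[length(groups)]]
    block <- unlist(strata_series[cur], use.names = FALSE)
    nxt <- strata_series[[j]]
    res <- if (test_family == "rank") {
      mann_whitney(block, nxt, mode = "asymptotic",
                   labels = c(paste(labs[cur], collapse = "+"), labs[j]))
    } else {
      gaussian_compare(list(block, nxt),
                       labels = c(paste(labs[cur], collapse = "+"), labs[j]))
    }
    p_adj <- min(1, m_adj * res$p_value)
    sig <- p_adj < alpha
    cmp <- rbind(cmp, data.frame(
      block = res$labels[1], stratum = labs[j], test = res$test,
      statistic = res$statistic, p_value = res$p_value, p_adjusted = p_adj,
      significant = sig, stringsAsFactors = FALSE))
    if (sig) groups[[length(groups) + 1L]] <- j
    else groups[[length(groups)]] <- c(cur, j)
  }
  out <- list(strata = labs,
              groups = lapply(groups, function(i) labs[i]),
              group_labels = vapply(groups, function(i) .merge_label(labs[i]), ""),
              comparisons = cmp, alpha = alpha, test_family = test_family,
              adjust = adjust)
  class(out) <- "merge_plan"
  out
}

# "20-49" + "50-59" -> "20-59"; singleton labels pass through.
.merge_label <- function(labels) {
  if (length(labels) == 1L) return(labels)
  first <- labels[1L]; last <- labels[length(labels)]
  lo <- sub("^>=?", "", sub("-.*$", "", first))
  if (startsWith(last, ">=")) paste0(">=", lo)
  else paste0(lo, "-", sub("^.*-", "", last))
}

#' @export
print.merge_plan <- function(x, ...) {
  cat("Merge plan (", x$test_family, " family, alpha = ", x$alpha,
      if (x$adjust != "none") paste0(", ", x$adjust, "-adjusted") else "",
      "):\n", sep = "")
  cat("  groups:", paste(x$group_labels, collapse = " | "), "\n")
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Age bounds of merged groups
#'
#' Maps the merged group labels of a [build_merge_plan()] result back to
#' inclusive age ranges using the stratum definitions.
#'
#' @param plan a `merge_plan`.
#' @param strata the [age_strata()] the plan's labels came from.
#' @return data.frame with `label`, `lower`, `upper` per merged group.
#' @export
merge_plan_bounds <- function(plan, strata = age_strata()) {
  stopifnot(inherits(plan, "merge_plan"))
  do.call(rbind, lapply(seq_along(plan$groups), function(i) {
    members <- plan$groups[[i]]
    rows <- strata[strata$label %in% members, ]
    data.frame(label = plan$group_labels[i], lower = min(rows$lower),
               upper = max(rows$upper), stringsAsFactors = FALSE)
  }))
}
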