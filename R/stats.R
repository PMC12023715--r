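# Nonparametric comparison harness: normality-test selection, Mann-Whitney U
# for two groups, Kruskal-Wallis with Dunn's post hoc comparisons for three
# or more, with significance stars at 0.05 / 0.01 / 0.001 / 0.0001.

#' Significance stars
#'
#' @param p numeric p-values.
#' @return character vector: `****` for p < 0.0001, `***` < 0.001,
#'   `**` < 0.01, `*` < 0.05, `ns` otherwise.
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Normality check with sample-size dependent test selection
#'
#' Shapiro-Wilk for samples of fewer than 50 values, Kolmogorov-Smirnov
#' (Lilliefors-corrected, i.e. with estimated mean and sd) for 50 or more.
#'
#' @param x numeric sample (n >= 3).
#' @return list with `test_name` (`"shapiro_wilk"` or
#'   `"kolmogorov_smirnov"`), `p`, and `n`.
#' @export
normality_check <- function(x) {
  n <- length(x)
  assert_that(n >= 3, "normality check needs at least 3 values")
  if (stats::sd(x) == 0) {
    # degenerate (constant) sample: neither test is defined
    return(list(test_name = if (n < 50) "shapiro_wilk" else "kolmogorov_smirnov",
                p = NA_real_, n = n))
  }
  if (n < 50) {
    list(test_name = "shapiro_wilk", p = stats::shapiro.test(x)$p.value, n = n)
  } else {
    list(test_name = "kolmogorov_smirnov", p = nortest::lillie.test(x)$p.value,
         n = n)
  }
}

#' Two-group comparison with the Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test with exact small-sample
#' p-values where feasible (no ties, n < 50) and the normal approximation
#' with continuity correction otherwise. Per-group normality checks are
#' attached when both groups have at least 3 values.
#'
#' @param a,b numeric samples.
#' @param group_names length-2 character vector of group labels.
#' @return A `group_comparison`: `test = "mann_whitney"`, `statistic` (U for
#'   the first sample), `p_value`, `stars`, `groups`, `normality`.
#' @export
compare_two <- function(a, b, group_names = c("a", "b")) {
  assert_that(length(a) > 0 && length(b) > 0, "both samples must be nonempty")
  ht <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  normality <- if (length(a) >= 3 && length(b) >= 3)
    stats::setNames(list(normality_check(a), normality_check(b)), group_names)
  else NULL
  structure(list(test = "mann_whitney",
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 stars = p_stars(ht$p.value),
                 groups = stats::setNames(list(a, b), group_names),
                 normality = normality),
            class = "group_comparison")
}

#' Multi-group comparison: Kruskal-Wallis with Dunn's post hoc test
#'
#' Kruskal-Wallis omnibus test (tie-corrected) followed by Dunn's pairwise
#' z-tests on mean ranks with multiplicity adjustment over all pairs
#' (Bonferroni by default, matching common statistics-software behavior;
#' any method of [stats::p.adjust()] may be chosen).
#'
#' @param groups named list of (>= 3) numeric samples.
#' @param p_adjust_method multiplicity adjustment passed to
#'   [stats::p.adjust()] (default `"bonferroni"`).
#' @return A `group_comparison` with `test = "kruskal_dunn"`, the omnibus
#'   `statistic` (H) and `p_value`, per-group `normality`, and `pairwise`, a
#'   data.frame of Dunn comparisons (`group1`, `group2`, `z`, `p_unadjusted`,
#'   `p_adjusted`, `stars`).
#' @export
compare_many <- function(groups, p_adjust_method = "bonferroni") {
  assert_that(is.list(groups) && length(groups) >= 3,
              "compare_many needs at least 3 groups; use compare_two for 2")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  kw <- stats::kruskal.test(x, g)

  # Dunn's z statistics on mean ranks with tie-corrected variance
  n_tot <- length(x)
  rk <- rank(x)
  mean_rank <- tapply(rk, g, mean)
  n_i <- tapply(rk, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  pairs <- utils::combn(names(groups), 2)
  pw <- apply(pairs, 2, function(pr) {
    se <- sqrt((n_tot * (n_tot + 1) / 12 - tie_term) *
               (1 / n_i[[pr[1]]] + 1 / n_i[[pr[2]]]))
    z <- (mean_rank[[pr[1]]] - mean_rank[[pr[2]]]) / se
    data.frame(group1 = pr[1], group2 = pr[2], z = z,
               p_unadjusted = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, pw)
  pw$p_adjusted <- stats::p.adjust(pw$p_unadjusted, method = p_adjust_method)
  pw$stars <- p_stars(pw$p_adjusted)
  normality <- lapply(groups, function(v)
    if (length(v) >= 3) normality_check(v) else NULL)
  structure(list(test = "kruskal_dunn",
                 statistic = unname(kw$statistic),
                 p_value = kw$p.value,
                 stars = p_stars(kw$p.value),
                 groups = groups,
                 pairwise = pw,
                 normality = normality),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (x$test == "mann_whitney") {
    cat(sprintf("Mann-Whitney U = %g, p = %.4g %s\n",
                x$statistic, x$p_value, x$stars))
  } else {
    cat(sprintf("Kruskal-Wallis H = %.4g, p = %.4g %s\n",
                x$statistic, x$p_value, x$stars))
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}
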