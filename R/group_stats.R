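#' Mann-Whitney (Wilcoxon rank-sum) comparison of two groups
#'
#' Computes the Mann-Whitney U statistic for the first sample and its p value:
#' exact (by enumeration of rank assignments) when the combined sample size is
#' at most 12 and there are no ties, otherwise the normal approximation with
#' tie correction and continuity correction.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @param alternative `"two_sided"` (default), `"less"` or `"greater"`.
#' @param alpha Significance level (default 0.05).
#' @param labels Length-2 character vector naming the groups.
#' @return An object of class `group_comparison` with `test_name`
#'   (`"mann_whitney"`), `group_labels`, `statistic` (U), `p_value`,
#'   `significant`, `alpha`, `exact`.
#' @export
#' @examples
#' mann_whitney_test(c(1, 2, 3), c(4, 5, 6))$p_value  # exact: 0.1
mann_whitney_test <- function(a, b,
                              alternative = c("two_sided", "less", "greater"),
                              alpha = 0.05,
                              labels = c("a", "b")) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L || anyNA(a) || anyNA(b)) {
    stop_invalid("both groups must be non-empty with no missing values")
  }
  assert_fraction(alpha, "alpha")
  n <- length(a) + length(b)
  has_ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- n <= 12L && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(
    a, b,
    alternative = sub("_", ".", alternative),
    exact = use_exact, correct = TRUE
  ))
  res <- list(test_name = "mann_whitney",
              group_labels = labels,
              statistic = unname(wt$statistic),
              p_value = unname(wt$p.value),
              significant = unname(wt$p.value) < alpha,
              alpha = alpha,
              exact = use_exact,
              alternative = alternative)
  structure(res, class = "group_comparison")
}

#' One-way ANOVA with Bonferroni-adjusted post hoc comparisons
#'
#' Classical one-way analysis of variance
#' (`F = (SSB / df_between) / (SSW / df_within)` via [stats::aov()]) followed
#' by pairwise post hoc tests over all `k (k - 1) / 2` group pairs with
#' Bonferroni adjustment. Pairwise tests are Welch two-sample t tests by
#' default, or Mann-Whitney tests.
#'
#' @param groups Named list of at least 2 numeric vectors, each with at least
#'   2 values.
#' @param alpha Significance level (default 0.05).
#' @param pairwise `"welch_t"` (default) or `"mann_whitney"`.
#' @return An object of class `group_comparison` with `test_name`
#'   (`"anova_bonferroni"`), `statistic` (F), `df` (between, within),
#'   `p_value` (omnibus), `degenerate` (TRUE when within-group variance is
#'   zero with unequal means), and a `pairwise` data.frame with columns
#'   `pair`, `raw_p`, `adjusted_p`, `significant`.
#' @export
#' @examples
#' one_way_anova_bonferroni(list(g1 = c(0, 1), g2 = c(2, 3)))$statistic  # F = 8
one_way_anova_bonferroni <- function(groups, alpha = 0.05,
                                     pairwise = c("welch_t", "mann_whitney")) {
  pairwise <- match.arg(pairwise)
  assert_fraction(alpha, "alpha")
  if (!is.list(groups) || length(groups) < 2L) {
    stop_invalid("`groups` must be a list of at least 2 numeric vectors")
  }
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop_invalid("every group needs at least 2 values")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), sizes), levels = names(groups))

  fit <- stats::aov(value ~ grp)
  tab <- summary(fit)[[1L]]
  ssb <- tab["grp", "Sum Sq"]; ssw <- tab["Residuals", "Sum Sq"]
  df1 <- tab["grp", "Df"]; df2 <- tab["Residuals", "Df"]
  tot <- ssb + ssw
  no_between <- ssb <= 1e-12 * max(tot, 1)
  degenerate <- ssw <= 1e-12 * max(tot, 1) && !no_between
  if (degenerate) {
    f_stat <- Inf
    p <- 0
  } else if (no_between && ssw <= 1e-12 * max(tot, 1)) {
    f_stat <- 0
    p <- 1
  } else {
    f_stat <- unname(tab["grp", "F value"])
    p <- unname(tab["grp", "Pr(>F)"])
  }

  pairs <- utils::combn(names(groups), 2L)
  m <- ncol(pairs)
  raw_p <- numeric(m)
  for (j in seq_len(m)) {
    x <- groups[[pairs[1L, j]]]; y <- groups[[pairs[2L, j]]]
    raw_p[j] <- if (pairwise == "welch_t") {
      if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        if (mean(x) == mean(y)) 1 else 0
      } else {
        stats::t.test(x, y, var.equal = FALSE)$p.value
      }
    } else {
      mann_whitney_test(x, y)$p_value
    }
  }
  adj_p <- stats::p.adjust(raw_p, method = "bonferroni")
  pw <- data.frame(pair = paste(pairs[1L, ], pairs[2L, ], sep = " vs "),
                   raw_p = raw_p, adjusted_p = adj_p,
                   significant = adj_p < alpha,
                   stringsAsFactors = FALSE)
  structure(list(test_name = "anova_bonferroni",
                 group_labels = names(groups),
                 statistic = f_stat,
                 df = c(between = df1, within = df2),
                 p_value = p,
                 degenerate = degenerate,
                 pairwise = pw,
                 pairwise_test = pairwise,
                 alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (x$test_name == "mann_whitney") {
    cat(sprintf("Mann-Whitney (%s): U = %g, p = %.4g (%s at alpha = %g)\n",
                x$alternative, x$statistic, x$p_value,
                if (x$significant) "significant" else "not significant",
                x$alpha))
  } else {
    cat(sprintf("One-way ANOVA: F(%d, %d) = %g, p = %.4g%s\n",
                x$df[["between"]], x$df[["within"]], x$statistic, x$p_value,
                if (isTRUE(x$degenerate)) " [degenerate: zero within-group variance]" else ""))
    cat(sprintf("Bonferroni post hoc (%s):\n", x$pairwise_test))
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Percent change relative to a reference condition
#'
#' `(reference - other) / reference * 100`: a positive value is a reduction
#' relative to the reference, a negative value an increase.
#'
#' @param reference_mean Reference condition mean (non-zero).
#' @param other_mean Other condition mean.
#' @return Percent reduction.
#' @export
#' @examples
#' relative_change(2, 1)  # 50 percent reduction
relative_change <- function(reference_mean, other_mean) {
  assert_number(reference_mean, "reference_mean")
  assert_number(other_mean, "other_mean")
  if (reference_mean == 0) stop_invalid("`reference_mean` must be non-zero")
  (reference_mean - other_mean) / reference_mean * 100
}
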