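# Nonparametric cohort statistics: Mann-Whitney U, Spearman trends,
# 2x2 contingency, median [IQR] group comparisons.

new_stat_result <- function(test_name, statistic, p_value, effect_direction,
                            n_per_group, estimate = NA_real_, ...) {
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, effect_direction = effect_direction,
                 n_per_group = n_per_group, estimate = estimate, ...),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s\n", x$test_name))
  cat(sprintf("  statistic = %.4g, p = %.4g, direction = %+d, n = %s\n",
              x$statistic, x$p_value, x$effect_direction,
              paste(x$n_per_group, collapse = " vs ")))
  if (!is.na(x$estimate)) cat(sprintf("  estimate  = %.4g\n", x$estimate))
  invisible(x)
}

#' Mann-Whitney U test (Wilcoxon rank-sum)
#'
#' Two-sided rank-sum comparison of two independent samples. When both
#' groups have at most 10 observations and there are no ties, the p-value
#' comes from the exact null distribution of U; otherwise from the normal
#' approximation with the tie-corrected variance (no continuity
#' correction). The statistic reported is `U` for the first group;
#' `effect_direction` is the sign of `U - mn/2` (+1 when the first group
#' tends larger).
#'
#' @param group_a,group_b Numeric vectors (both nonempty).
#' @param exact `"auto"` (default rule above), `"yes"` or `"no"`.
#' @return A `stat_result`.
#' @export
mann_whitney <- function(group_a, group_b, exact = c("auto", "yes", "no")) {
  exact <- match.arg(exact)
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) == 0 || length(b) == 0) vf_stop("both groups must be nonempty")
  m <- length(a); n <- length(b); N <- m + n
  pooled <- c(a, b)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  ties <- as.numeric(table(pooled))
  has_ties <- any(ties > 1)
  use_exact <- switch(exact,
                      auto = m <= 10 && n <= 10 && !has_ties,
                      yes = TRUE, no = FALSE)
  if (use_exact && has_ties) {
    warning("ties present: exact Mann-Whitney distribution is not valid; ",
            "using the tie-corrected normal approximation", call. = FALSE)
    use_exact <- FALSE
  }
  if (use_exact) {
    p <- min(1, 2 * min(stats::pwilcox(U, m, n),
                        1 - stats::pwilcox(U - 1, m, n)))
  } else {
    sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- if (sigma2 > 0) (U - m * n / 2) / sqrt(sigma2) else 0
    p <- 2 * stats::pnorm(-abs(z))
  }
  new_stat_result("Mann-Whitney U", statistic = U, p_value = p,
                  effect_direction = sign(U - m * n / 2),
                  n_per_group = c(m, n),
                  estimate = stats::median(a) - stats::median(b),
                  exact = use_exact)
}

#' Spearman rank correlation for segment trends
#'
#' Tie-corrected Spearman rho (mid-ranks then Pearson) with a two-sided
#' p-value from the t approximation `t = rho sqrt((n-2)/(1-rho^2))`. A
#' trend with `|rho| > 0.5` is labelled `"strong"`. Degenerate inputs
#' (either variable constant) are returned as a flagged result with
#' `degenerate = TRUE`, `rho = NA` and `p = NA` rather than propagating
#' NaN.
#'
#' @param segment_indices Numeric x values (e.g. segment index 1..15,
#'   pooled across patients).
#' @param values Numeric y values, same length (>= 3 pairs).
#' @return A `stat_result` with `estimate = rho` and a `strength` label.
#' @export
spearman_trend <- function(segment_indices, values) {
  x <- as.numeric(segment_indices); y <- as.numeric(values)
  vf_assert(length(x) == length(y), "x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  vf_assert(n >= 3, "need at least 3 paired observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(new_stat_result("Spearman rank correlation", statistic = NA_real_,
                           p_value = NA_real_, effect_direction = 0L,
                           n_per_group = n, estimate = NA_real_,
                           degenerate = TRUE, strength = "undefined"))
  }
  rho <- stats::cor(rank(x), rank(y))
  rho <- clamp(rho, -1, 1)
  if (abs(rho) == 1) {
    tstat <- sign(rho) * Inf; p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  new_stat_result("Spearman rank correlation", statistic = tstat,
                  p_value = p, effect_direction = sign(rho),
                  n_per_group = n, estimate = rho, degenerate = FALSE,
                  strength = if (abs(rho) > 0.5) "strong" else "weak")
}

#' Pearson linear correlation for segment trends
#'
#' Companion to [spearman_trend()] for the "linear correlation with
#' segmenting" reading of the trend analysis; same degenerate handling.
#'
#' @inheritParams spearman_trend
#' @return A `stat_result` with `estimate = r`.
#' @export
pearson_trend <- function(segment_indices, values) {
  x <- as.numeric(segment_indices); y <- as.numeric(values)
  vf_assert(length(x) == length(y), "x and y lengths differ")
  n <- length(x)
  vf_assert(n >= 3, "need at least 3 paired observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(new_stat_result("Pearson correlation", statistic = NA_real_,
                           p_value = NA_real_, effect_direction = 0L,
                           n_per_group = n, estimate = NA_real_,
                           degenerate = TRUE, strength = "undefined"))
  }
  r <- clamp(stats::cor(x, y), -1, 1)
  if (abs(r) == 1) {
    tstat <- sign(r) * Inf; p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  new_stat_result("Pearson correlation", statistic = tstat, p_value = p,
                  effect_direction = sign(r), n_per_group = n, estimate = r,
                  degenerate = FALSE,
                  strength = if (abs(r) > 0.5) "strong" else "weak")
}

#' High-velocity segment contingency test
#'
#' 2x2 comparison of flagged-segment proportions between two groups:
#' Pearson chi-squared without continuity correction (default), or
#' Fisher's exact test. Percentages are reported to one decimal.
#'
#' @param flagged_a,total_a Flagged and total segment counts, group A.
#' @param flagged_b,total_b Same for group B.
#' @param method `"chisq"` (default) or `"fisher"`.
#' @return A `stat_result` with `percent = c(a, b)` and the `table`.
#' @export
high_velocity_contingency <- function(flagged_a, total_a, flagged_b, total_b,
                                      method = c("chisq", "fisher")) {
  method <- match.arg(method)
  vf_assert(total_a > 0 && total_b > 0, "totals must be > 0")
  vf_assert(flagged_a >= 0 && flagged_b >= 0 &&
            flagged_a <= total_a && flagged_b <= total_b,
            "flagged counts must lie in [0, total]")
  tab <- rbind(a = c(flagged = flagged_a, not = total_a - flagged_a),
               b = c(flagged = flagged_b, not = total_b - flagged_b))
  pct <- round(100 * c(flagged_a / total_a, flagged_b / total_b), 1)
  if (method == "chisq") {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(E == 0)) { # a margin is empty: no association testable
      stat <- 0; p <- 1
    } else {
      stat <- sum((tab - E)^2 / E)
      p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    }
    name <- "Pearson chi-squared (2x2, no continuity correction)"
  } else {
    ft <- stats::fisher.test(tab)
    stat <- unname(ft$estimate)
    p <- ft$p.value
    name <- "Fisher exact (2x2)"
  }
  new_stat_result(name, statistic = stat, p_value = p,
                  effect_direction = sign(flagged_a / total_a - flagged_b / total_b),
                  n_per_group = c(total_a, total_b),
                  estimate = pct[1] - pct[2], percent = pct, table = tab)
}

#' Compare a variable between ruptured and unruptured subjects
#'
#' Median and interquartile range per group (linear-interpolation
#' quantiles, R type 7) plus a [mann_whitney()] test, matching the
#' median [IQR] + rank-sum reporting convention of the cohort tables.
#'
#' @param cohort A [cohort_table()]-style data frame with a logical
#'   `rupture` column.
#' @param variable Column name to compare.
#' @param exact Passed to [mann_whitney()].
#' @return List with `summary` (data frame: group, n, median, q1, q3) and
#'   `test` (a `stat_result`), class `group_comparison`.
#' @export
compare_groups <- function(cohort, variable, exact = "auto") {
  vf_assert(variable %in% names(cohort),
            sprintf("unknown variable '%s'", variable))
  vf_assert("rupture" %in% names(cohort), "cohort needs a 'rupture' column")
  a <- cohort[[variable]][cohort$rupture]
  b <- cohort[[variable]][!cohort$rupture]
  q <- function(x) stats::quantile(x, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  qa <- q(a); qb <- q(b)
  structure(list(
    variable = variable,
    summary = data.frame(group = c("ruptured", "unruptured"),
                         n = c(length(a), length(b)),
                         median = c(qa[1], qb[1]),
                         q1 = c(qa[2], qb[2]),
                         q3 = c(qa[3], qb[3])),
    test = mann_whitney(a, b, exact = exact)),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%s:\n", x$variable))
  for (i in 1:2) {
    cat(sprintf("  %-10s %6.2f [%6.2f, %6.2f] (n = %d)\n",
                s$group[i], s$median[i], s$q1[i], s$q3[i], s$n[i]))
  }
  cat(sprintf("  Mann-Whitney p = %.4g\n", x$test$p_value))
  invisible(x)
}
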