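test_that("Mann-Whitney: identical, separated and swapped groups", {
  same <- rep(c(1, 2, 3), 4)
  res <- suppressWarnings(mann_whitney(same, same))
  expect_gte(res$p_value, 0.99)

  a <- 11:16; b <- 1:5  # fully separated, 6 vs 5, no ties
  sep <- mann_whitney(a, b)
  expect_true(sep$exact)
  expect_equal(sep$p_value, 2 / 462, tolerance = 1e-12)
  expect_equal(sep$p_value, oracle_mw_exact_p(a, b), tolerance = 1e-12)
  swapped <- mann_whitney(b, a)
  expect_equal(swapped$p_value, sep$p_value)
  expect_equal(swapped$effect_direction, -sep$effect_direction)
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("Mann-Whitney agrees with independent reference routes", {
  set.seed(31)
  # exact small-sample path vs wilcox.test exact and vs enumeration
  for (i in 1:10) {
    a <- rnorm(sample(4:9, 1))
    b <- rnorm(sample(4:9, 1), mean = runif(1, -1, 1))
    mine <- mann_whitney(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$p_value, oracle_mw_exact_p(a, b), tolerance = 1e-12)
  }
  # tie-corrected normal approximation vs wilcox.test without continuity
  for (i in 1:10) {
    a <- sample(1:6, 15, replace = TRUE)
    b <- sample(1:6, 18, replace = TRUE) + rbinom(18, 1, 0.5)
    mine <- mann_whitney(a, b)
    ref <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
    expect_false(mine$exact)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Spearman trend: perfect monotone, ties, invariance, degenerate", {
  x <- 1:12
  expect_equal(spearman_trend(x, 2 * x + 3)$estimate, 1)
  expect_equal(spearman_trend(x, -x^3)$estimate, -1)

  set.seed(8)
  for (i in 1:10) {
    xi <- sample(1:15, 60, replace = TRUE)   # pooled segment indices with ties
    yi <- round(rnorm(60, xi, 5), 1)
    res <- spearman_trend(xi, yi)
    brute <- cor(rank(xi), rank(yi))         # rank-then-Pearson oracle
    expect_equal(res$estimate, brute, tolerance = 1e-12)
    ref <- suppressWarnings(cor.test(xi, yi, method = "spearman"))
    expect_equal(res$estimate, unname(ref$estimate), tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(spearman_trend(xi, exp(yi / 10))$estimate, res$estimate)
  }
  deg <- spearman_trend(1:10, rep(2, 10))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$estimate))
  expect_error(spearman_trend(1:2, 1:2), "at least 3")
})

test_that("high-velocity contingency on the printed 2x2 counts", {
  res <- high_velocity_contingency(36, 90, 11, 75)
  expect_equal(res$percent, c(40.0, 14.7))
  expect_lt(res$p_value, 0.001)
  # four-cell expected-count oracle
  O <- c(36, 54, 11, 64)
  rows <- c(90, 75); cols <- c(47, 118); N <- 165
  E <- c(rows[1] * cols[1], rows[1] * cols[2], rows[2] * cols[1],
         rows[2] * cols[2]) / N
  expect_equal(res$statistic, sum((O - E)^2 / E), tolerance = 1e-9)
  fish <- high_velocity_contingency(36, 90, 11, 75, method = "fisher")
  expect_true(fish$p_value >= 0 && fish$p_value <= 1)
  expect_lt(fish$p_value, 0.001)

  same <- high_velocity_contingency(10, 50, 20, 100)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(high_velocity_contingency(10, 5, 1, 5), "flagged")
})

test_that("compare_groups reports type-7 median [IQR] plus the rank test", {
  df <- data.frame(rupture = rep(c(TRUE, FALSE), c(8, 8)),
                   v = c(1:8, 1:8 + 100))
  cmp <- compare_groups(df, "v")
  expect_equal(cmp$summary$q1, c(2.75, 102.75))
  expect_equal(cmp$summary$q3, c(6.25, 106.25))
  expect_equal(cmp$summary$median, c(4.5, 104.5))
  expect_lt(cmp$test$p_value, 0.05)
  expect_error(compare_groups(df, "missing_var"), "unknown variable")

  one <- data.frame(rupture = c(TRUE, TRUE, FALSE, FALSE), v = c(3, 3, 7, 7))
  cmp1 <- suppressWarnings(compare_groups(one, "v"))
  expect_equal(cmp1$summary$median, c(3, 7))
  expect_equal(cmp1$summary$q1, cmp1$summary$q3)  # IQR collapses
})
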