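test_that("Mann-Whitney exact p matches hand enumeration on the canonical case", {
  r <- mann_whitney_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)   # 2/20 of C(6,3) rank assignments
  expect_true(r$exact)
  expect_false(r$significant)
})

test_that("identical samples give p = 1 and swapping groups preserves p", {
  a <- c(1.2, 3.4, 2.2, 5.1)
  r <- mann_whitney_test(a, a)
  expect_equal(r$p_value, 1)
  set.seed(9)
  x <- rnorm(6); y <- rnorm(8, 0.5)
  expect_equal(mann_whitney_test(x, y)$p_value,
               mann_whitney_test(y, x)$p_value)
  expect_error(mann_whitney_test(numeric(0), y), "non-empty")
})

test_that("exact Mann-Whitney agrees with the enumeration oracle on random small samples", {
  set.seed(101)
  for (i in 1:100) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    ## continuous draws: no ties, combined n <= 10
    x <- round(rnorm(na), 6); y <- round(rnorm(nb, sample(c(-1, 0, 1), 1)), 6)
    r <- mann_whitney_test(x, y)
    expect_true(r$exact)
    expect_equal(r$p_value, mw_enumeration_p(x, y), tolerance = 1e-12)
  }
})

test_that("ties or large samples switch to the corrected normal approximation", {
  r <- mann_whitney_test(c(1, 2, 2, 3), c(2, 4, 5, 6))
  expect_false(r$exact)
  expect_true(r$p_value >= 0 && r$p_value <= 1)
  big <- mann_whitney_test(rnorm(10), rnorm(10))
  expect_false(big$exact)
})

test_that("one-way ANOVA reproduces the hand-computed F and handles degenerate input", {
  r <- one_way_anova_bonferroni(list(g1 = c(0, 1), g2 = c(2, 3)))
  expect_equal(r$statistic, 8)                      # SSB = 4, SSW = 1, df (1, 2)
  expect_equal(unname(r$df), c(1, 2))
  expect_equal(r$p_value, stats::pf(8, 1, 2, lower.tail = FALSE))

  same <- one_way_anova_bonferroni(list(a = c(1, 1), b = c(1, 1), c = c(1, 1)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  degen <- one_way_anova_bonferroni(list(a = c(1, 1), b = c(2, 2)))
  expect_true(degen$degenerate)
  expect_identical(degen$statistic, Inf)

  expect_error(one_way_anova_bonferroni(list(a = 1:3)), "at least 2")
  expect_error(one_way_anova_bonferroni(list(a = 1:3, b = 2)), "at least 2")
})

test_that("ANOVA F is invariant under affine rescaling of the data", {
  set.seed(3)
  g <- list(a = rnorm(6), b = rnorm(6, 1), c = rnorm(6, 2))
  f0 <- one_way_anova_bonferroni(g)$statistic
  shifted <- lapply(g, function(x) 3.7 + x)
  scaled <- lapply(g, function(x) 2.5 * x)
  expect_equal(one_way_anova_bonferroni(shifted)$statistic, f0,
               tolerance = 1e-9)
  expect_equal(one_way_anova_bonferroni(scaled)$statistic, f0,
               tolerance = 1e-9)
})

test_that("Bonferroni adjustment multiplies by the pair count, never below raw, capped at 1", {
  set.seed(14)
  g <- list(a = rnorm(5), b = rnorm(5, 0.8), c = rnorm(5, 1.6))
  r <- one_way_anova_bonferroni(g)
  expect_equal(nrow(r$pairwise), 3L)
  expect_equal(r$pairwise$adjusted_p,
               pmin(1, r$pairwise$raw_p * 3))
  expect_true(all(r$pairwise$adjusted_p >= r$pairwise$raw_p))
  expect_true(all(r$pairwise$adjusted_p <= 1))
  expect_identical(r$pairwise$significant, r$pairwise$adjusted_p < r$alpha)
  ## a raw p of 0.02 over 3 pairs is not significant after adjustment
  expect_false(0.02 * 3 < 0.05)

  rmw <- one_way_anova_bonferroni(g, pairwise = "mann_whitney")
  expect_equal(nrow(rmw$pairwise), 3L)
})

test_that("relative change follows the reduction sign convention", {
  expect_equal(relative_change(2, 1), 50)
  expect_equal(relative_change(1.5, 1.5), 0)
  expect_equal(relative_change(1, 1.5), -50)
  expect_error(relative_change(0, 1), "non-zero")
})
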