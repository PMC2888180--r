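test_that("contour length and end-to-end distance match hand-computed chains", {
  expect_equal(contour_length(cbind(0, 0:4)), 4)
  expect_equal(contour_length(rbind(c(0, 0), c(1, 1), c(2, 2))), 2 * sqrt(2))
  expect_equal(contour_length(rbind(c(0, 0), c(1, 1), c(1, 2))), sqrt(2) + 1)

  expect_equal(end_to_end_distance(cbind(0, 0:4)), 4)
  loop <- rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0), c(0, 0))
  expect_equal(end_to_end_distance(loop), 0)
  lchain <- rbind(c(0, 0), c(0, 1), c(0, 2), c(1, 2), c(2, 2))
  expect_equal(end_to_end_distance(lchain), 2 * sqrt(2))

  expect_error(contour_length(rbind(c(0, 0))), "2 rows")
  expect_error(end_to_end_distance(rbind(c(0, 0))), "2 rows")
})

test_that("segment objects maintain the R <= L invariant", {
  set.seed(5)
  for (s in wlc_segments(50, 60, 15)) {
    expect_lte(s$end_to_end_distance, s$contour_length + 1e-12)
    expect_gte(s$end_to_end_distance, 0)
  }
})

test_that("bending ratio is exactly 1 for straight segments and 4/pi^2 for a semicircle", {
  straight <- lapply(1:5, function(i) segment(cbind(i, 0:(10 + i))))
  expect_identical(bending_ratio(straight)$bending_ratio, 1)

  th <- seq(0, pi, length.out = 1e4)
  arc <- segment(cbind(50 * sin(th), 50 * cos(th)))
  expect_equal(bending_ratio(list(arc))$bending_ratio, 4 / pi^2,
               tolerance = 1e-3)

  expect_error(bending_ratio(list()), "empty")
})

test_that("bending ratio of a WLC ensemble matches the closed-form R^2 law", {
  set.seed(21)
  lp <- 50; s <- 100; n <- 2000
  segs <- wlc_segments(n, s, lp)
  br <- bending_ratio(segs)
  expected <- (4 * lp * s - 8 * lp^2 * (1 - exp(-s / (2 * lp)))) / s^2
  r2 <- vapply(segs, function(x) x$end_to_end_distance^2, numeric(1))
  se <- sd(r2 / s^2) / sqrt(n)
  expect_lt(abs(br$bending_ratio - expected), 3 * se)
  ## the two averaging conventions differ but both sit near the law
  br2 <- bending_ratio(segs, method = "mean_of_ratios")
  expect_equal(br2$bending_ratio, br$bending_ratio, tolerance = 0.05)
})

test_that("both persistence-length estimators recover the generating Lp", {
  set.seed(33)
  segs <- wlc_segments(300, 200, 50)
  e1 <- estimate_persistence_length(segs, "end_to_end_fit")
  e2 <- estimate_persistence_length(segs, "tangent_correlation")
  expect_true(e1$estimable); expect_true(e2$estimable)
  expect_lt(abs(e1$persistence_length - 50) / 50, 0.15)
  expect_lt(abs(e2$persistence_length - 50) / 50, 0.15)
  expect_lt(abs(e1$persistence_length - e2$persistence_length) /
              e1$persistence_length, 0.10)
  expect_gt(e1$stderr, 0)
  expect_gt(e1$rmse, 0)
})

test_that("all-straight ensembles are flagged non-estimable, not fitted", {
  straight <- lapply(1:25, function(i) segment(cbind(0, 0:80 + i)))
  est <- estimate_persistence_length(straight)
  expect_false(est$estimable)
  expect_identical(est$persistence_length, Inf)
})

test_that("few segments trigger a warning", {
  set.seed(2)
  segs <- wlc_segments(5, 80, 30)
  expect_warning(estimate_persistence_length(segs), "fewer than 20")
})

test_that("morphometry is invariant under rotation and translation", {
  set.seed(8)
  segs <- wlc_segments(60, 120, 40)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- lapply(segs, function(s) segment(s$chain %*% R +
                                              matrix(c(55, -12), nrow(s$chain),
                                                     2, byrow = TRUE)))
  expect_equal(bending_ratio(moved)$bending_ratio,
               bending_ratio(segs)$bending_ratio, tolerance = 1e-9)
  e0 <- suppressWarnings(estimate_persistence_length(segs))
  e1 <- suppressWarnings(estimate_persistence_length(moved))
  expect_equal(e1$persistence_length, e0$persistence_length, tolerance = 1e-6)
})

test_that("condition summaries populate every field and convert units", {
  set.seed(13)
  segs <- wlc_segments(100, 150, 50)
  res <- summarize_condition(segs, pixel_scale = 10)
  expect_equal(res$n_segments, 100L)
  expect_equal(res$bending_ratio,
               res$mean_sq_end_to_end / res$mean_sq_contour)
  expect_true(res$bending_ratio > 0 && res$bending_ratio <= 1)
  expect_true(res$estimable)
  expect_equal(res$persistence_length_nm, res$persistence_length * 10)
  expect_gt(res$median_segment_length, 0)

  one <- summarize_condition(list(segment(cbind(0, 0:20))))
  expect_identical(one$bending_ratio, 1)
  expect_false(one$estimable)
})
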