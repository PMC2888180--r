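test_that("infinite persistence length gives a collinear path with exact step spacing", {
  set.seed(1)
  p <- sample_wlc_path(c(10, 5), pi / 6, total_length = 40,
                       persistence_length = Inf, step_length = 1)
  expect_equal(nrow(p$points), 41L)
  steps <- diff(p$points)
  expect_equal(sqrt(rowSums(steps^2)), rep(1, 40), tolerance = 1e-12)
  ## collinearity: all cross products with the first step vanish
  cross <- steps[, 1] * steps[1, 2] - steps[, 2] * steps[1, 1]
  expect_lt(max(abs(cross)), 1e-9)
})

test_that("point count and determinism follow the sampling contract", {
  set.seed(7)
  p1 <- sample_wlc_path(c(0, 0), 0, total_length = 33.9,
                        persistence_length = 20, step_length = 2)
  expect_equal(nrow(p1$points), floor(33.9 / 2) + 1)
  set.seed(7)
  p2 <- sample_wlc_path(c(0, 0), 0, total_length = 33.9,
                        persistence_length = 20, step_length = 2)
  expect_identical(p1$points, p2$points)
  expect_error(sample_wlc_path(c(0, 0), 0, -5, 50), "total_length")
  expect_error(sample_wlc_path(c(0, 0), 0, 50, 0), "persistence_length")
  expect_error(sample_wlc_path(c(0, 0), 0, 0.5, 50, step_length = 1),
               "total_length")
})

test_that("sampled chains obey the planar WLC tangent-correlation and R^2 laws", {
  set.seed(42)
  lp <- 30; s <- 60; n <- 3000
  cosv <- numeric(n); r2 <- numeric(n)
  for (i in seq_len(n)) {
    p <- sample_wlc_path(c(0, 0), stats::runif(1, 0, 2 * pi), s, lp, 1)
    pts <- p$points
    d1 <- pts[2, ] - pts[1, ]
    d2 <- pts[nrow(pts), ] - pts[nrow(pts) - 1, ]
    cosv[i] <- cos(atan2(d2[1], d2[2]) - atan2(d1[1], d1[2]))
    r2[i] <- end_to_end_distance(pts)^2
  }
  ## tangent decorrelation over s - 1 steps
  exp_cos <- exp(-(s - 1) / (2 * lp))
  expect_lt(abs(mean(cosv) - exp_cos), 3 * sd(cosv) / sqrt(n))
  exp_r2 <- 4 * lp * s - 8 * lp^2 * (1 - exp(-s / (2 * lp)))
  expect_lt(abs(mean(r2) - exp_r2), 3 * sd(r2) / sqrt(n))
})

test_that("short-chain limit is ballistic: R^2 approaches s^2 for s << Lp", {
  set.seed(3)
  s <- 10; lp <- 1000
  r2 <- replicate(500, {
    p <- sample_wlc_path(c(0, 0), 0, s, lp, 1)
    end_to_end_distance(p$points)^2
  })
  expect_equal(mean(r2) / s^2, 1, tolerance = 0.01)
})

test_that("branching adds paths rooted on their parents at the stated rate", {
  set.seed(11)
  base <- lapply(1:2, function(i) sample_wlc_path(c(100, 100), i, 50, 40, 1))

  expect_identical(add_branches(base, 0, 10), base)

  one <- list(sample_wlc_path(c(0, 0), 0, 10, Inf, 1))  # 10 steps
  forced <- add_branches(one, 1, 5)
  expect_length(forced, 11L)  # 10 branches + original
  for (br in forced[-1]) {
    expect_equal(br$parent_index, 1L)
    ## branch root lies on a parent point
    d <- sqrt((one[[1]]$points[, 1] - br$points[1, 1])^2 +
              (one[[1]]$points[, 2] - br$points[1, 2])^2)
    expect_lt(min(d), 1e-9)
  }

  ## binomial rate check: p = 0.02 over 200 x 100 = 2e4 steps
  set.seed(12)
  many <- lapply(1:200, function(i) sample_wlc_path(c(0, 0), 0, 100, 50, 1))
  out <- add_branches(many, 0.02, 10)
  n_br <- length(out) - length(many)
  expected <- 2e4 * 0.02
  expect_lt(abs(n_br - expected), 3 * sqrt(2e4 * 0.02 * 0.98))
})
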