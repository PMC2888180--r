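test_that("a constant image yields no edges", {
  img <- gray_image(matrix(0.5, 32, 32))
  e <- detect_edges(img)
  expect_equal(sum(e), 0L)
})

test_that("a vertical intensity step yields a single vertical edge line", {
  m <- matrix(0.2, 32, 32)
  m[, 17:32] <- 0.8
  e <- detect_edges(gray_image(m), gaussian_sigma = 1,
                    low_threshold = 0.05, high_threshold = 0.1)
  fg <- which(unclass(e), arr.ind = TRUE)
  interior <- fg[fg[, 1] > 2 & fg[, 1] < 31, , drop = FALSE]
  expect_gt(nrow(interior), 20)
  ## one column, at the step, one pixel wide
  expect_equal(length(unique(interior[, 2])), 1L)
  expect_true(unique(interior[, 2]) %in% 16:17)
})

test_that("threshold validation rejects bad hysteresis parameters", {
  img <- gray_image(matrix(0.5, 16, 16))
  expect_error(detect_edges(img, low_threshold = 1.2), "low_threshold")
  expect_error(detect_edges(img, low_threshold = 0.5, high_threshold = 0.2),
               "low_threshold")
  expect_error(detect_edges(img, gaussian_sigma = 0), "gaussian_sigma")
})

test_that("edges of a clean synthetic fibril lie within 2 px of the ground truth", {
  spec <- small_spec(noise_sd = 0)
  ds <- generate_dataset(spec, 1, seed = 8)
  e <- detect_edges(ds[[1]]$image)
  ## distance from every ground-truth point on-canvas to the nearest edge pixel
  dist_to_edge <- as.matrix(EBImage::distmap(1 - unclass(e) * 1))
  for (p in ds[[1]]$paths) {
    pts <- round(p$points) + 1
    on_canvas <- pts[, 1] >= 1 & pts[, 1] <= nrow(e) &
                 pts[, 2] >= 1 & pts[, 2] <= ncol(e)
    d <- dist_to_edge[pts[on_canvas, , drop = FALSE]]
    expect_lt(max(d), 2 + 1e-9)
  }
})

test_that("a solid 3-px bar thins to a single 1-px line", {
  bar <- matrix(FALSE, 16, 20)
  bar[7:9, 3:17] <- TRUE
  sk <- skeletonize_mask(bar)
  fg <- which(unclass(sk), arr.ind = TRUE)
  expect_equal(unique(fg[, 1]), 8L)
  expect_gt(nrow(fg), 10)
})

test_that("thinning preserves topology: an annulus becomes one closed loop", {
  n <- 40
  d <- sqrt(outer((1:n - 20.5)^2, (1:n - 20.5)^2, "+"))
  ann <- d >= 6 & d <= 12
  sk <- skeletonize_mask(ann)
  ## still one connected component
  expect_equal(max(label_components8(unclass(sk))), 1L)
  g <- build_skeleton_graph(sk)
  expect_equal(nrow(g$nodes), 1L)
  expect_equal(g$nodes$kind, "cycle-anchor")
  expect_length(g$chains, 1L)
})

test_that("skeletonization is idempotent and closing preserves component count", {
  spec <- small_spec(noise_sd = 0)
  ds <- generate_dataset(spec, 1, seed = 13)
  e <- detect_edges(ds[[1]]$image)
  closed <- close_edges(e, 2)
  sk <- skeletonize_mask(closed)
  expect_identical(unclass(skeletonize_mask(sk)), unclass(sk))
  expect_equal(max(label_components8(unclass(sk))),
               max(label_components8(unclass(closed))))
})

test_that("one clean fibril gives exactly one skeleton component", {
  spec <- synthetic_image_spec(image_height = 256, image_width = 256,
                               n_fibrils = 1, fibril_length = 90,
                               fibril_diameter = 3, noise_sd = 0)
  ds <- generate_dataset(spec, 1, seed = 17)
  sk <- close_and_skeletonize(detect_edges(ds[[1]]$image), closing_radius = 2)
  expect_equal(max(label_components8(unclass(sk))), 1L)
})

test_that("empty edge masks pass through the chain without error", {
  e <- binary_image(matrix(FALSE, 16, 16), "edges")
  sk <- close_and_skeletonize(e)
  expect_equal(sum(sk), 0L)
  g <- build_skeleton_graph(sk)
  expect_equal(nrow(g$nodes), 0L)
  expect_length(g$chains, 0L)
})
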