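test_that("a plus-shaped skeleton decomposes into 4 endpoints, 1 junction, 4 arms", {
  g <- build_skeleton_graph(plus_mask())
  expect_equal(sum(g$nodes$kind == "endpoint"), 4L)
  expect_equal(sum(g$nodes$kind == "junction"), 1L)
  expect_length(g$chains, 4L)
  expect_equal(g$chain_info$contour_length, rep(4, 4))
  expect_equal(g$chain_info$n_points, rep(5L, 4))
  segs <- extract_segments(g, min_segment_length = 0,
                           prune_spurs_shorter_than = 0)
  expect_length(segs, 4L)
})

test_that("a straight line is 2 endpoints and one chain", {
  g <- build_skeleton_graph(line_mask(10))
  expect_equal(sum(g$nodes$kind == "endpoint"), 2L)
  expect_equal(sum(g$nodes$kind == "junction"), 0L)
  expect_length(g$chains, 1L)
  expect_equal(g$chain_info$contour_length, 9)
})

test_that("a closed ring gets one cycle-anchor and one returning chain", {
  g <- build_skeleton_graph(ring_mask())
  expect_equal(nrow(g$nodes), 1L)
  expect_equal(g$nodes$kind, "cycle-anchor")
  expect_length(g$chains, 1L)
  ch <- g$chains[[1]]
  expect_identical(ch[1, ], ch[nrow(ch), ])       # returns to the anchor
  expect_equal(nrow(ch), sum(ring_mask()) + 1L)   # every ring pixel once
})

test_that("spur pruning removes the short stem of a T and keeps the bar halves", {
  g <- build_skeleton_graph(t_with_spur_mask())
  expect_equal(sum(g$nodes$kind == "endpoint"), 3L)
  expect_equal(sum(g$nodes$kind == "junction"), 1L)
  expect_length(g$chains, 3L)

  segs <- extract_segments(g, min_segment_length = 0,
                           prune_spurs_shorter_than = 5)
  expect_length(segs, 2L)
  lens <- sort(vapply(segs, `[[`, numeric(1), "contour_length"))
  expect_equal(lens, c(9, 10))
  ## both survivors are collinear with the bar (same row throughout)
  for (s in segs) expect_equal(unique(s$chain[, "row"]), 4)
})

test_that("min_segment_length larger than every chain empties the output", {
  g <- build_skeleton_graph(plus_mask())
  expect_length(extract_segments(g, min_segment_length = 100,
                                 prune_spurs_shorter_than = 0), 0L)
})

test_that("handshake and pixel-partition invariants hold on generated skeletons", {
  spec <- small_spec(n_fibrils = 4, branch_probability = 0.03)
  ds <- generate_dataset(spec, 2, seed = 23)
  cfg <- pipeline_config()
  for (i in seq_along(ds)) {
    ext <- extract_image(ds[[i]]$image, cfg)
    g <- ext$graph
    ci <- g$chain_info
    ## handshake: chain-node incidences = 2 x chains (dangling ends excluded)
    expect_equal(sum(ci$from_node > 0) + sum(ci$to_node > 0),
                 2L * nrow(ci) - sum(ci$to_node == 0))
    ## chain steps are king moves
    for (ch in g$chains) {
      st <- sqrt(rowSums(diff(ch)^2))
      expect_true(all(abs(st - 1) < 1e-9 | abs(st - sqrt(2)) < 1e-9))
    }
    ## partition: chain interiors are disjoint; interiors + node pixels +
    ## chain terminals cover the skeleton
    nr <- g$dim[1]
    interiors <- unlist(lapply(g$chains, function(ch) {
      if (nrow(ch) <= 2) return(integer(0))
      ix <- ch[-c(1, nrow(ch)), , drop = FALSE]
      ix[, 2] * nr + ix[, 1] + 1
    }))
    expect_equal(anyDuplicated(interiors), 0L)
    terminals <- unlist(lapply(g$chains, function(ch) {
      ix <- ch[c(1, nrow(ch)), , drop = FALSE]
      ix[, 2] * nr + ix[, 1] + 1
    }))
    covered <- unique(c(interiors, terminals))
    skel_px <- which(unclass(ext$skeleton))
    ## isolated single pixels are discarded by design; all other skeleton
    ## pixels must be accounted for
    cnt_mat <- ext$skeleton
    expect_true(all(covered %in% skel_px))
    expect_gte(length(covered), length(skel_px) - 2L)
  }
})

test_that("adjacent junction pixels merge into a single junction node", {
  ## two 3-way junction pixels side by side, each with two private arms
  m <- matrix(FALSE, 6, 7)
  m[3, 3] <- TRUE; m[3, 4] <- TRUE            # the adjacent junction pair
  m[1, 3] <- TRUE; m[2, 3] <- TRUE            # N arm of the left pixel
  m[4, 2] <- TRUE; m[5, 1] <- TRUE            # SW arm of the left pixel
  m[2, 5] <- TRUE; m[1, 6] <- TRUE            # NE arm of the right pixel
  m[4, 5] <- TRUE; m[5, 6] <- TRUE            # SE arm of the right pixel
  g <- build_skeleton_graph(m)
  expect_equal(sum(g$nodes$kind == "junction"), 1L)
  expect_equal(g$nodes$n_pixels[g$nodes$kind == "junction"], 2L)
  expect_equal(sum(g$nodes$kind == "endpoint"), 4L)
  expect_length(g$chains, 4L)
})
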