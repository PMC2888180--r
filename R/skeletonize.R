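## Guo-Hall thinning (two-subiteration, 1989), vectorized over the whole
## matrix. Neighbors: p2=N, p3=NE, p4=E, p5=SE, p6=S, p7=SW, p8=W, p9=NW,
## with row increasing downward and col increasing rightward.
guo_hall_thin <- function(mask) {
  m <- mask * 1L
  repeat {
    changed <- FALSE
    for (iter in 0:1) {
      p2 <- shift_mat(m, 1, 0)    # north neighbor value lands on the pixel
      p3 <- shift_mat(m, 1, -1)
      p4 <- shift_mat(m, 0, -1)
      p5 <- shift_mat(m, -1, -1)
      p6 <- shift_mat(m, -1, 0)
      p7 <- shift_mat(m, -1, 1)
      p8 <- shift_mat(m, 0, 1)
      p9 <- shift_mat(m, 1, 1)
      C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
           (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
      N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      N <- pmin(N1, N2)
      m3 <- if (iter == 0) ((p6 | p7 | !p9) & p8) else ((p2 | p3 | !p5) & p4)
      del <- m == 1L & C == 1 & N >= 2 & N <= 3 & !m3
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

#' Morphological closing of an edge mask
#'
#' Closes an edge mask with a disc structuring element. On ridge-like fibrils
#' the Canny detector responds with two parallel contours (one per side);
#' closing with a radius comparable to the fibril diameter fuses them into a
#' single solid band, so that thinning yields one centerline per fibril.
#'
#' @param mask A [binary_image] (provenance `"edges"`) or logical matrix.
#' @param closing_radius Disc radius in pixels (>= 0; 0 is a no-op).
#' @return A [binary_image] with provenance `"closed"`.
#' @export
close_edges <- function(mask, closing_radius = 2) {
  assert_number(closing_radius, "closing_radius", lower = 0)
  m <- unclass(as.matrix(mask)) * 1
  if (closing_radius > 0 && any(m > 0)) {
    brush <- EBImage::makeBrush(2L * as.integer(ceiling(closing_radius)) + 1L,
                                shape = "disc")
    m <- as.matrix(EBImage::closing(m, brush))
  }
  binary_image(m > 0, "closed")
}

#' Skeletonize a binary mask to one-pixel-wide centerlines
#'
#' Topology-preserving Guo-Hall thinning: iteratively removes contour pixels
#' whose deletion does not change local connectivity, until no pixel is
#' removable. Connected components and holes are preserved, and the operation
#' is idempotent on an already-thin skeleton.
#'
#' @param mask A [binary_image] or logical matrix.
#' @return A [binary_image] with provenance `"skeleton"`.
#' @export
skeletonize_mask <- function(mask) {
  m <- unclass(as.matrix(mask)) > 0
  binary_image(guo_hall_thin(m), "skeleton")
}

#' Close an edge mask and thin it to a skeleton
#'
#' The second stage of the extraction chain: fuse the Canny double-edge
#' response with a morphological closing, then thin to a one-pixel-wide
#' skeleton.
#'
#' @inheritParams close_edges
#' @return A [binary_image] with provenance `"skeleton"`.
#' @export
#' @examples
#' bar <- matrix(FALSE, 16, 16); bar[7:9, 3:14] <- TRUE
#' sum(close_and_skeletonize(binary_image(bar, "edges"), closing_radius = 0))
close_and_skeletonize <- function(mask, closing_radius = 2) {
  skeletonize_mask(close_edges(mask, closing_radius))
}

#' Otsu threshold segmentation of a fibril image
#'
#' Alternative first stage to [detect_edges()]: a global Otsu threshold on the
#' (optionally smoothed) intensity image, returning a solid foreground mask
#' that can be thinned directly. Useful for comparison with the Canny chain on
#' bright-ridge images.
#'
#' @param image A [gray_image] or matrix in `[0, 1]`.
#' @param gaussian_sigma Smoothing applied before thresholding (0 disables).
#' @return A [binary_image] with provenance `"closed"` (a solid mask, ready
#'   for [skeletonize_mask()]).
#' @export
threshold_fibrils <- function(image, gaussian_sigma = 1) {
  m <- unclass(as.matrix(image))
  assert_number(gaussian_sigma, "gaussian_sigma", lower = 0)
  if (gaussian_sigma > 0) {
    m <- as.matrix(EBImage::gblur(m, sigma = gaussian_sigma,
                                  boundary = "replicate"))
    m[m < 0] <- 0; m[m > 1] <- 1
  }
  thr <- EBImage::otsu(EBImage::Image(m))
  binary_image(m > thr, "closed")
}
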