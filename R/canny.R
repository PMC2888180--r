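#' Binary image container
#'
#' A logical matrix tagged with its provenance in the extraction chain:
#' `"edges"` (Canny output), `"closed"` (after morphological closing) or
#' `"skeleton"` (after thinning).
#'
#' @param pixels Logical matrix.
#' @param provenance One of `"edges"`, `"closed"`, `"skeleton"`.
#' @return An object of class `binary_image`.
#' @export
binary_image <- function(pixels, provenance = c("edges", "closed", "skeleton")) {
  provenance <- match.arg(provenance)
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "logical"
  if (anyNA(pixels)) stop_invalid("binary image must not contain NA")
  structure(pixels, provenance = provenance,
            class = c("binary_image", "matrix"))
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("<binary_image:%s> %d x %d px, %d foreground\n",
              attr(x, "provenance"), nrow(x), ncol(x), sum(x)))
  invisible(x)
}

## Sobel gradients of a matrix; returns list(gx, gy, mag) with gx along +col
## and gy along +row. EBImage::filter2 indexes images [x, y], i.e. the first
## matrix dimension is horizontal; kernels below are written for [row, col].
sobel_gradient <- function(m) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE) / 8
  ky <- t(kx)
  gx <- as.matrix(EBImage::filter2(m, kx, boundary = "replicate"))
  gy <- as.matrix(EBImage::filter2(m, ky, boundary = "replicate"))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Canny edge detection
#'
#' The full Canny chain: Gaussian smoothing, Sobel gradient magnitude and
#' direction, non-maximum suppression perpendicular to the edge, and
#' double-threshold hysteresis (8-connected weak-edge components are kept only
#' if they touch a strong pixel).
#'
#' When `low_threshold`/`high_threshold` are `NULL` they default to the 0.70
#' and 0.90 quantiles of the gradient magnitude. Because fibril fields are
#' sparse — almost all pixels are featureless background — the quantiles are
#' taken over magnitudes above a robust noise floor (twice the median positive
#' magnitude) rather than over every pixel, so the defaults adapt to contrast
#' without drowning in the noise distribution.
#'
#' @param image A [gray_image] (or plain matrix in `[0, 1]`).
#' @param gaussian_sigma Smoothing scale in pixels (> 0).
#' @param low_threshold,high_threshold Absolute hysteresis thresholds on the
#'   gradient magnitude, in `[0, 1]` with `low <= high`; `NULL` for the
#'   quantile defaults.
#' @param threshold_quantiles Length-2 quantiles used when thresholds are
#'   `NULL`.
#' @return A [binary_image] with provenance `"edges"`.
#' @export
#' @examples
#' img <- gray_image(matrix(rep(c(0.2, 0.8), each = 8 * 16), 16, 16))
#' sum(detect_edges(img, low_threshold = 0.05, high_threshold = 0.1))
detect_edges <- function(image, gaussian_sigma = 1,
                         low_threshold = NULL, high_threshold = NULL,
                         threshold_quantiles = c(0.70, 0.90)) {
  m <- unclass(as.matrix(image))
  assert_positive(gaussian_sigma, "gaussian_sigma")
  if (!is.null(low_threshold)) assert_fraction(low_threshold, "low_threshold")
  if (!is.null(high_threshold)) assert_fraction(high_threshold, "high_threshold")
  if (!is.null(low_threshold) && !is.null(high_threshold) &&
      low_threshold > high_threshold) {
    stop_invalid("`low_threshold` (%g) must be <= `high_threshold` (%g)",
                 low_threshold, high_threshold)
  }

  sm <- as.matrix(EBImage::gblur(m, sigma = gaussian_sigma,
                                 boundary = "replicate"))
  g <- sobel_gradient(sm)
  ## round away FFT convolution noise so that plateau ties in the
  ## non-maximum suppression are exact and a constant image stays edge-free
  mag <- signif(g$mag, 10)
  if (max(mag) < 1e-12) {
    return(binary_image(matrix(FALSE, nrow(m), ncol(m)), "edges"))
  }

  if (is.null(low_threshold) || is.null(high_threshold)) {
    pos <- mag[mag > 0]
    if (length(pos) == 0L) {
      return(binary_image(matrix(FALSE, nrow(m), ncol(m)), "edges"))
    }
    floor_ <- 2 * stats::median(pos)
    sig <- mag[mag > floor_]
    if (length(sig) < 2L) sig <- pos
    qs <- stats::quantile(sig, threshold_quantiles, names = FALSE)
    if (is.null(low_threshold)) low_threshold <- qs[1L]
    if (is.null(high_threshold)) high_threshold <- qs[2L]
  }
  if (low_threshold > high_threshold) {
    stop_invalid("`low_threshold` (%g) must be <= `high_threshold` (%g)",
                 low_threshold, high_threshold)
  }

  ## non-maximum suppression: compare each pixel with its two neighbors along
  ## the quantized gradient direction (0, 45, 90, 135 degrees)
  ang <- atan2(g$gy, g$gx)                    # (-pi, pi], 0 = +col
  sector <- floor(((ang + pi / 8) %% pi) / (pi / 4)) %% 4
  nb <- function(dr, dc) shift_mat(mag, dr, dc, fill = 0)
  ## strict on the positive-direction neighbor so plateau ties keep one pixel
  keep <-
    (sector == 0 & mag >= nb(0, -1) & mag > nb(0, 1)) |     # grad horizontal
    (sector == 1 & mag >= nb(-1, -1) & mag > nb(1, 1)) |    # grad diag down
    (sector == 2 & mag >= nb(-1, 0) & mag > nb(1, 0)) |     # grad vertical
    (sector == 3 & mag >= nb(-1, 1) & mag > nb(1, -1))      # grad diag up
  nms <- keep & mag > 0

  strong <- nms & mag >= high_threshold
  weak <- nms & mag >= low_threshold
  if (!any(strong)) {
    return(binary_image(matrix(FALSE, nrow(m), ncol(m)), "edges"))
  }
  lab <- label_components8(weak)
  keep_labels <- unique(lab[strong])
  edges <- weak & matrix(lab %in% keep_labels, nrow(lab), ncol(lab))
  binary_image(edges, "edges")
}
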