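#' Grayscale image container
#'
#' A `gray_image` wraps a 2-D matrix of intensities normalized to `[0, 1]`,
#' with an optional physical pixel scale in nanometers per pixel. Rows index
#' the vertical (downward) axis, columns the horizontal axis.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`, at least 8x8.
#' @param pixel_scale Optional physical scale (nm per pixel).
#' @return An object of class `gray_image` (a matrix with attributes).
#' @export
gray_image <- function(pixels, pixel_scale = NULL) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || nrow(pixels) < 8L || ncol(pixels) < 8L) {
    stop_invalid("`pixels` must be a numeric matrix of at least 8 x 8")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    stop_invalid("intensities must lie in [0, 1] with no missing values")
  }
  if (!is.null(pixel_scale)) assert_positive(pixel_scale, "pixel_scale")
  structure(pixels, pixel_scale = pixel_scale, class = c("gray_image", "matrix"))
}

#' @export
print.gray_image <- function(x, ...) {
  ps <- attr(x, "pixel_scale")
  cat(sprintf("<gray_image> %d x %d px%s, intensity [%.3f, %.3f]\n",
              nrow(x), ncol(x),
              if (is.null(ps)) "" else sprintf(" at %g nm/px", ps),
              min(x), max(x)))
  invisible(x)
}

#' Read a grayscale image from TIFF or PNG
#'
#' Reads a single-channel 8- or 16-bit TIFF or PNG and rescales intensities to
#' `[0, 1]` by the bit-depth maximum. RGB images are accepted only when all
#' channels are identical. The physical pixel scale is never guessed from file
#' metadata; pass it explicitly.
#'
#' @param path Path to a `.tif`, `.tiff` or `.png` file.
#' @param pixel_scale Optional nm-per-pixel scale to attach.
#' @return A [gray_image].
#' @export
read_gray_image <- function(path, pixel_scale = NULL) {
  if (!file.exists(path)) stop_invalid("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop_invalid("unsupported image format '%s' (use TIFF or PNG): %s",
                 ext, path)
  )
  if (length(dim(arr)) == 3L) {
    ch <- dim(arr)[3L]
    first <- arr[, , 1L]
    for (k in seq_len(ch)[-1L]) {
      if (k == 4L) next  # opaque alpha plane is tolerated
      if (max(abs(arr[, , k] - first)) > 1e-9) {
        stop_invalid(
          "multi-channel image with non-identical channels is not grayscale: %s",
          path)
      }
    }
    arr <- first
  }
  gray_image(arr, pixel_scale = pixel_scale)
}

#' Write a grayscale image as 16-bit TIFF or PNG
#'
#' @param image A [gray_image].
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @return The path, invisibly.
#' @export
write_gray_image <- function(image, path) {
  stopifnot(inherits(image, "gray_image"))
  m <- unclass(image)
  attr(m, "pixel_scale") <- NULL
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(m, path, bits.per.sample = 16L),
    png = png::writePNG(m, path),
    stop_invalid("unsupported image format '%s' (use TIFF or PNG): %s",
                 ext, path)
  )
  invisible(path)
}
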