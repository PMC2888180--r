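#' Specification of a synthetic fibril image
#'
#' Bundles every parameter of the synthetic generator. The defaults describe a
#' sparse SEM-like validation field: a 512 x 512 canvas holding a few thin
#' bright fibrils (diameter 2.5 px, i.e. 25 nm at the default 10 nm/px scale)
#' of persistence length 50 px over a dark background, lightly blurred and
#' corrupted by additive Gaussian noise. Fibril density is kept low enough that
#' fibril-fibril crossings are rare, so extracted segments can be matched to
#' individual ground-truth paths; denser, more tangled fields are produced by
#' raising `n_fibrils` and `branch_probability`.
#'
#' @param image_height,image_width Canvas size in pixels.
#' @param n_fibrils Number of primary fibrils (>= 0).
#' @param fibril_length Contour length of each fibril (pixels).
#' @param persistence_length Worm-like-chain persistence length (pixels; may be
#'   `Inf` for straight fibrils).
#' @param step_length Chain discretization step (pixels).
#' @param branch_probability Per-step probability of nucleating a branch.
#' @param branch_length Contour length of each branch (pixels).
#' @param fibril_diameter Drawn fibril width (pixels).
#' @param blur_sigma Gaussian blur applied after drawing (pixels; 0 disables).
#' @param noise_sd Additive Gaussian noise standard deviation (intensity
#'   fraction in `[0, 1]`; 0 disables).
#' @param background_level Background intensity fraction in `[0, 1]`.
#' @param pixel_scale Optional physical scale (nm per pixel).
#' @param seed Optional integer seed recorded with generated datasets.
#' @return An object of class `synthetic_image_spec` (a validated list).
#' @export
synthetic_image_spec <- function(image_height = 512L,
                                 image_width = 512L,
                                 n_fibrils = 3L,
                                 fibril_length = 100,
                                 persistence_length = 50,
                                 step_length = 1,
                                 branch_probability = 0,
                                 branch_length = 40,
                                 fibril_diameter = 2.5,
                                 blur_sigma = 1,
                                 noise_sd = 0.05,
                                 background_level = 0.15,
                                 pixel_scale = 10,
                                 seed = NULL) {
  assert_number(image_height, "image_height", lower = 8)
  assert_number(image_width, "image_width", lower = 8)
  assert_number(n_fibrils, "n_fibrils", lower = 0)
  assert_positive(fibril_length, "fibril_length")
  assert_positive(persistence_length, "persistence_length", allow_inf = TRUE)
  assert_positive(step_length, "step_length")
  assert_fraction(branch_probability, "branch_probability")
  assert_positive(branch_length, "branch_length")
  assert_positive(fibril_diameter, "fibril_diameter")
  assert_number(blur_sigma, "blur_sigma", lower = 0)
  assert_fraction(noise_sd, "noise_sd")
  assert_fraction(background_level, "background_level")
  if (!is.null(pixel_scale)) assert_positive(pixel_scale, "pixel_scale")
  if (!is.null(seed)) assert_number(seed, "seed")
  structure(
    list(image_height = as.integer(image_height),
         image_width = as.integer(image_width),
         n_fibrils = as.integer(n_fibrils),
         fibril_length = fibril_length,
         persistence_length = persistence_length,
         step_length = step_length,
         branch_probability = branch_probability,
         branch_length = branch_length,
         fibril_diameter = fibril_diameter,
         blur_sigma = blur_sigma,
         noise_sd = noise_sd,
         background_level = background_level,
         pixel_scale = pixel_scale,
         seed = seed),
    class = "synthetic_image_spec"
  )
}

#' Rasterize fibril paths into a noisy grayscale image
#'
#' Draws each path as a bright ridge of width `fibril_diameter` (intensity 1)
#' over `background_level`, applies a Gaussian blur of `blur_sigma`, adds
#' Gaussian noise of standard deviation `noise_sd`, and clips to `[0, 1]`.
#' Path coordinates outside the canvas are clipped, not an error. The function
#' consumes the current R random stream for the noise.
#'
#' @param paths List of [fibril_path] objects (may be empty).
#' @param spec A [synthetic_image_spec].
#' @return A [gray_image] of size `image_height` x `image_width`.
#' @export
rasterize_fibrils <- function(paths, spec) {
  stopifnot(inherits(spec, "synthetic_image_spec"), is.list(paths))
  h <- spec$image_height; w <- spec$image_width
  img <- matrix(spec$background_level, h, w)
  radius <- spec$fibril_diameter / 2
  rmax <- ceiling(radius)
  off <- expand.grid(dr = -rmax:rmax, dc = -rmax:rmax)
  for (p in paths) {
    pts <- p$points
    ## resample the polyline densely so stamped disks overlap into a tube
    seg <- sqrt(rowSums(diff(pts)^2))
    cum <- c(0, cumsum(seg))
    s <- seq(0, cum[length(cum)], by = 0.35)
    rr <- stats::approx(cum, pts[, 1L], xout = s)$y
    cc <- stats::approx(cum, pts[, 2L], xout = s)$y
    ## integer pixels within `radius` of any sample point
    pr <- rep(round(rr), each = nrow(off)) + off$dr
    pc <- rep(round(cc), each = nrow(off)) + off$dc
    d2 <- (pr - rep(rr, each = nrow(off)))^2 + (pc - rep(cc, each = nrow(off)))^2
    keep <- d2 <= radius^2 & pr >= 0 & pr <= h - 1 & pc >= 0 & pc <= w - 1
    if (any(keep)) {
      img[cbind(pr[keep] + 1L, pc[keep] + 1L)] <- 1
    }
  }
  if (spec$blur_sigma > 0) {
    img <- as.matrix(EBImage::gblur(img, sigma = spec$blur_sigma))
  }
  if (spec$noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  gray_image(img, pixel_scale = spec$pixel_scale)
}

## sample the ground-truth paths of one image from the current random stream
sample_image_paths <- function(spec) {
  paths <- vector("list", spec$n_fibrils)
  for (i in seq_len(spec$n_fibrils)) {
    start <- c(stats::runif(1, 0, spec$image_height - 1),
               stats::runif(1, 0, spec$image_width - 1))
    direction <- stats::runif(1, 0, 2 * pi)
    paths[[i]] <- sample_wlc_path(start, direction,
                                  total_length = spec$fibril_length,
                                  persistence_length = spec$persistence_length,
                                  step_length = spec$step_length)
  }
  add_branches(paths, spec$branch_probability, spec$branch_length)
}

#' Generate a synthetic dataset of fibril images with ground truth
#'
#' Produces `n_images` independent fields: for each, fibril starting points
#' are drawn uniformly over the canvas and initial directions uniformly over
#' `[0, 2 pi)` (isotropy, no preferred orientation), worm-like-chain paths are
#' sampled, branches added, and the field rasterized.
#'
#' @param spec A [synthetic_image_spec].
#' @param n_images Number of images (>= 1).
#' @param seed Integer seed; defaults to `spec$seed`. The whole dataset is
#'   deterministic given `spec` and `seed`.
#' @return A list of class `fibril_dataset`: each element is a list with
#'   components `image` (a [gray_image]) and `paths` (list of [fibril_path]).
#'   The spec and seed are attached as attributes.
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_image_spec(image_height = 64,
#'                                             image_width = 64,
#'                                             n_fibrils = 1,
#'                                             fibril_length = 40),
#'                        n_images = 1, seed = 7)
#' ds[[1]]$image
generate_dataset <- function(spec, n_images, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  assert_number(n_images, "n_images", lower = 1)
  if (is.null(seed)) stop_invalid("a seed is required (in `spec` or `seed`)")
  set.seed(as.integer(seed))
  out <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    paths <- sample_image_paths(spec)
    image <- rasterize_fibrils(paths, spec)
    out[[i]] <- list(image = image, paths = paths)
  }
  structure(out, spec = spec, seed = as.integer(seed),
            class = "fibril_dataset")
}
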