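#' Ground-truth fibril path
#'
#' A `fibril_path` is an ordered planar polyline sampled from a discrete
#' worm-like chain, together with the parameters that generated it. It is the
#' ground truth against which skeleton extraction and persistence-length
#' estimation are validated.
#'
#' Coordinates are continuous `(row, col)` pixel positions with pixel centers
#' at integers and the row axis increasing downward; every raster operation in
#' the package uses this single convention.
#'
#' @param points Numeric matrix with columns `row`, `col` (>= 2 points);
#'   consecutive points must be `step_length` apart.
#' @param true_persistence_length Persistence length (pixels) used to generate
#'   the path; `Inf` marks a straight path.
#' @param step_length Spacing of consecutive points (pixels).
#' @param parent_index Index of the path this one branched from, or `NA`.
#' @return An object of class `fibril_path`.
#' @export
fibril_path <- function(points, true_persistence_length, step_length,
                        parent_index = NA_integer_) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L || nrow(points) < 2L) {
    stop_invalid("`points` must be a numeric matrix with >= 2 rows and 2 columns")
  }
  colnames(points) <- c("row", "col")
  assert_positive(true_persistence_length, "true_persistence_length",
                  allow_inf = TRUE)
  assert_positive(step_length, "step_length")
  d <- sqrt(rowSums(diff(points)^2))
  if (any(abs(d - step_length) > 1e-9 * max(1, step_length))) {
    stop_invalid("consecutive points must be `step_length` = %g apart",
                 step_length)
  }
  structure(
    list(points = points,
         true_persistence_length = true_persistence_length,
         step_length = step_length,
         parent_index = parent_index),
    class = "fibril_path"
  )
}

#' @export
print.fibril_path <- function(x, ...) {
  cat(sprintf("<fibril_path> %d points, step %g px, Lp %s px%s\n",
              nrow(x$points), x$step_length,
              format(x$true_persistence_length),
              if (is.na(x$parent_index)) "" else
                sprintf(", branch of path %d", x$parent_index)))
  invisible(x)
}

#' Sample a planar worm-like-chain fibril path
#'
#' Draws a discrete two-dimensional worm-like chain: starting at `start` with
#' tangent angle `direction`, each step of length `step_length` turns by an
#' angle drawn from a zero-mean Gaussian with variance
#' `step_length / persistence_length`. This yields the planar tangent
#' correlation `<cos theta(s)> = exp(-s / (2 Lp))` and the closed-form
#' mean-squared end-to-end distance
#' `<R^2(s)> = 4 Lp s - 8 Lp^2 (1 - exp(-s / (2 Lp)))`.
#'
#' An infinite `persistence_length` gives a perfectly straight (collinear)
#' path. The function consumes the current R random stream; seed it with
#' [set.seed()] (or use [generate_dataset()], which manages seeds) for
#' reproducibility.
#'
#' @param start Numeric length-2 `(row, col)` starting coordinate (pixels).
#' @param direction Initial tangent angle in radians (0 points along +col;
#'   angles increase toward +row, i.e. clockwise on screen).
#' @param total_length Contour length to sample (pixels).
#' @param persistence_length Persistence length `Lp` (pixels); may be `Inf`.
#' @param step_length Discretization step (pixels), default 1.
#' @return A [fibril_path] with `floor(total_length / step_length) + 1` points.
#' @export
#' @examples
#' set.seed(1)
#' p <- sample_wlc_path(c(0, 0), 0, total_length = 50, persistence_length = 25)
#' nrow(p$points)
sample_wlc_path <- function(start, direction, total_length,
                            persistence_length, step_length = 1) {
  if (!is.numeric(start) || length(start) != 2L || any(!is.finite(start))) {
    stop_invalid("`start` must be a finite numeric (row, col) pair")
  }
  assert_number(direction, "direction")
  assert_positive(total_length, "total_length")
  assert_positive(persistence_length, "persistence_length", allow_inf = TRUE)
  assert_positive(step_length, "step_length")
  if (total_length < step_length) {
    stop_invalid("`total_length` (%g) must be >= `step_length` (%g)",
                 total_length, step_length)
  }
  n_steps <- floor(total_length / step_length)
  turn_sd <- if (is.finite(persistence_length)) {
    sqrt(step_length / persistence_length)
  } else 0
  ## the first step leaves along `direction`; each later step turns once
  turns <- if (turn_sd > 0) stats::rnorm(n_steps - 1L, 0, turn_sd) else
    numeric(n_steps - 1L)
  angles <- direction + c(0, cumsum(turns))
  rows <- start[1] + c(0, cumsum(step_length * sin(angles)))
  cols <- start[2] + c(0, cumsum(step_length * cos(angles)))
  fibril_path(cbind(row = rows, col = cols),
              true_persistence_length = persistence_length,
              step_length = step_length)
}

#' Add branch fibrils to a set of paths
#'
#' Emulates a branched/tangled fibril organization: at each step of each input
#' path, with probability `branch_probability`, a new worm-like-chain path of
#' contour length `branch_length` is nucleated at that point. The branch
#' take-off angle is the parent's local tangent plus a turn drawn from the same
#' Gaussian turning-angle distribution used along the chain, and the branch
#' inherits the parent's persistence length and step length. Branches do not
#' themselves branch.
#'
#' @param paths List of [fibril_path] objects.
#' @param branch_probability Per-step branching probability in `[0, 1]`.
#' @param branch_length Contour length of each branch (pixels).
#' @return The input list followed by the new branch paths, each with
#'   `parent_index` set to the index of its parent in `paths`.
#' @export
add_branches <- function(paths, branch_probability, branch_length) {
  stopifnot(is.list(paths))
  assert_fraction(branch_probability, "branch_probability")
  assert_positive(branch_length, "branch_length")
  if (length(paths) == 0L || branch_probability == 0) return(paths)
  out <- paths
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    pts <- p$points
    n_steps <- nrow(pts) - 1L
    hit <- which(stats::runif(n_steps) < branch_probability)
    for (j in hit) {
      tangent <- atan2(pts[j + 1L, 1L] - pts[j, 1L],
                       pts[j + 1L, 2L] - pts[j, 2L])
      turn_sd <- if (is.finite(p$true_persistence_length)) {
        sqrt(p$step_length / p$true_persistence_length)
      } else 0
      takeoff <- tangent + if (turn_sd > 0) stats::rnorm(1, 0, turn_sd) else 0
      br <- sample_wlc_path(pts[j, ], takeoff,
                            total_length = max(branch_length, p$step_length),
                            persistence_length = p$true_persistence_length,
                            step_length = p$step_length)
      br$parent_index <- i
      out[[length(out) + 1L]] <- br
    }
  }
  out
}
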