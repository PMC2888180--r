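#' Contour length of an ordered coordinate chain
#'
#' Sum of Euclidean distances between consecutive points. On a skeleton chain
#' every step is a king-move of length 1 or `sqrt(2)` pixels; the function
#' accepts any ordered planar polyline.
#'
#' @param chain Numeric matrix with columns `(row, col)` and at least 2 rows.
#' @return Contour length in pixels.
#' @export
#' @examples
#' contour_length(rbind(c(0, 0), c(1, 1), c(1, 2)))  # sqrt(2) + 1
contour_length <- function(chain) {
  chain <- as.matrix(chain)
  if (!is.numeric(chain) || nrow(chain) < 2L || ncol(chain) != 2L) {
    stop_invalid("`chain` must be a numeric matrix with >= 2 rows of (row, col)")
  }
  sum(sqrt(rowSums(diff(chain)^2)))
}

#' End-to-end distance of an ordered coordinate chain
#'
#' Euclidean distance between the first and last points; zero for a closed
#' loop.
#'
#' @inheritParams contour_length
#' @return End-to-end distance in pixels.
#' @export
end_to_end_distance <- function(chain) {
  chain <- as.matrix(chain)
  if (!is.numeric(chain) || nrow(chain) < 2L || ncol(chain) != 2L) {
    stop_invalid("`chain` must be a numeric matrix with >= 2 rows of (row, col)")
  }
  sqrt(sum((chain[nrow(chain), ] - chain[1L, ])^2))
}

#' Traced skeleton line segment
#'
#' Wraps an ordered pixel chain with its two derived lengths. The invariant
#' `contour_length >= end_to_end_distance >= 0` always holds.
#'
#' @param chain Numeric matrix of ordered `(row, col)` coordinates (>= 2 rows).
#' @return An object of class `segment` with elements `chain`,
#'   `contour_length`, `end_to_end_distance`.
#' @export
segment <- function(chain) {
  chain <- as.matrix(chain)
  structure(
    list(chain = chain,
         contour_length = contour_length(chain),
         end_to_end_distance = end_to_end_distance(chain)),
    class = "segment"
  )
}

#' @export
print.segment <- function(x, ...) {
  cat(sprintf("<segment> %d points, L = %.2f px, R = %.2f px\n",
              nrow(x$chain), x$contour_length, x$end_to_end_distance))
  invisible(x)
}

#' Per-segment metrics table
#'
#' @param segments List of [segment] objects.
#' @return data.frame with `segment_id`, `n_points`, `contour_length_px`,
#'   `end_to_end_px`.
#' @export
segments_table <- function(segments) {
  data.frame(
    segment_id = seq_along(segments),
    n_points = vapply(segments, function(s) nrow(s$chain), integer(1)),
    contour_length_px = vapply(segments, `[[`, numeric(1), "contour_length"),
    end_to_end_px = vapply(segments, `[[`, numeric(1), "end_to_end_distance")
  )
}

#' Bending ratio of a set of segments
#'
#' The bending ratio is the mean-squared end-to-end distance divided by the
#' mean-squared contour length, `(sum R_i^2 / n) / (sum L_i^2 / n)`. It equals
#' 1 when every segment is perfectly straight and decreases as segments curve
#' or tangle. The default is this ratio of means (the literal definition); a
#' per-segment mean of `R_i^2 / L_i^2` is available for sensitivity analysis.
#'
#' @param segments Non-empty list of [segment] objects.
#' @param method `"ratio_of_means"` (default) or `"mean_of_ratios"`.
#' @return A list with `bending_ratio`, `n_segments`, `mean_sq_end_to_end`,
#'   `mean_sq_contour`.
#' @export
#' @examples
#' s <- segment(cbind(0, 0:9))
#' bending_ratio(list(s))$bending_ratio  # straight: exactly 1
bending_ratio <- function(segments,
                          method = c("ratio_of_means", "mean_of_ratios")) {
  method <- match.arg(method)
  if (!is.list(segments) || length(segments) == 0L) {
    stop_invalid("bending ratio is not estimable from an empty segment list")
  }
  L2 <- vapply(segments, function(s) s$contour_length^2, numeric(1))
  R2 <- vapply(segments, function(s) s$end_to_end_distance^2, numeric(1))
  br <- switch(method,
               ratio_of_means = mean(R2) / mean(L2),
               mean_of_ratios = mean(R2 / L2))
  list(bending_ratio = br, n_segments = length(segments),
       mean_sq_end_to_end = mean(R2), mean_sq_contour = mean(L2))
}

## closed-form planar worm-like-chain mean-squared end-to-end distance
wlc_r2 <- function(s, lp) {
  4 * lp * s - 8 * lp^2 * (1 - exp(-s / (2 * lp)))
}

## Arc positions along a chain, as used by the persistence-length estimators.
## King-move pixel chains systematically overestimate the length of the
## underlying smooth curve; the classical corrected step weights for digitized
## curves (0.948 per orthogonal step, 1.343 per diagonal step; Kulpa / Dorst &
## Smeulders) remove most of that inflation. Continuous chains are summed
## exactly. Segment$contour_length keeps the literal king-move sum.
arc_positions <- function(chain) {
  st <- sqrt(rowSums(diff(chain)^2))
  ## lattice chains have integer coordinates and king-move steps; a continuous
  ## chain sampled at unit steps must not be shrunk
  if (length(st) && all(chain == round(chain)) &&
      all(abs(st - 1) < 1e-9 | abs(st - sqrt(2)) < 1e-9)) {
    st <- ifelse(abs(st - 1) < 1e-9, 0.948, 1.343)
  }
  c(0, cumsum(st))
}

## accumulate (s, value) pairs into bins of `width`; returns per-bin means
bin_means <- function(s, v, width) {
  idx <- floor(s / width) + 1L
  n <- tabulate(idx)
  sums_v <- unname(rowsum(v, idx))
  sums_s <- unname(rowsum(s, idx))
  keep <- which(n > 0L)
  data.frame(s = sums_s[, 1L] / n[keep],
             mean = sums_v[, 1L] / n[keep],
             n = n[keep])
}

## (s, R^2) pairs over internal sub-chains of one segment, all start points,
## lags strided so no segment contributes more than ~80 lag series
e2e_pairs <- function(chain, max_arc_fraction) {
  arc <- arc_positions(chain)
  n <- nrow(chain)
  smax <- max_arc_fraction * arc[n]
  max_lag <- n - 1L
  stride <- max(1L, ceiling(max_lag / 80))
  out_s <- vector("list", 0L); out_v <- vector("list", 0L)
  for (k in seq(1L, max_lag, by = stride)) {
    i <- seq_len(n - k)
    s <- arc[i + k] - arc[i]
    ok <- s <= smax
    if (!any(ok)) next
    d2 <- (chain[i + k, 1L] - chain[i, 1L])^2 +
          (chain[i + k, 2L] - chain[i, 2L])^2
    out_s[[length(out_s) + 1L]] <- s[ok]
    out_v[[length(out_v) + 1L]] <- d2[ok]
  }
  list(s = unlist(out_s), v = unlist(out_v))
}

## (s, cos dtheta) pairs from chord-estimated tangent angles of one segment
tangent_pairs <- function(chain, max_arc_fraction, window) {
  arc <- arc_positions(chain)
  n <- nrow(chain)
  mean_step <- arc[n] / (n - 1L)
  w <- max(1L, round(window / mean_step))
  if (n <= w + 1L) return(list(s = numeric(0), v = numeric(0)))
  i <- seq_len(n - w)
  ang <- atan2(chain[i + w, 1L] - chain[i, 1L],
               chain[i + w, 2L] - chain[i, 2L])
  pos <- (arc[i] + arc[i + w]) / 2          # chord midpoint arc position
  m <- length(ang)
  smax <- max_arc_fraction * arc[n]
  stride <- max(1L, ceiling((m - 1L) / 80))
  out_s <- vector("list", 0L); out_v <- vector("list", 0L)
  for (k in seq(1L, m - 1L, by = stride)) {
    j <- seq_len(m - k)
    s <- pos[j + k] - pos[j]
    ok <- s <= smax & s >= window          # below the window is pure chord overlap
    if (!any(ok)) next
    ## chord-overlap correction: for chord-averaged directions the angular
    ## variance at midpoint separation s is (s - w/3)/Lp, so the effective
    ## separation is shifted by one third of the window
    out_s[[length(out_s) + 1L]] <- s[ok] - window / 3
    out_v[[length(out_v) + 1L]] <- cos(ang[j + k] - ang[j])[ok]
  }
  list(s = unlist(out_s), v = unlist(out_v))
}

#' Estimate persistence length from traced segments
#'
#' Two estimators for the planar worm-like-chain persistence length `Lp`:
#' \describe{
#'   \item{`end_to_end_fit`}{Every internal sub-chain of every segment, up to
#'     arc separation `max_arc_fraction` times its contour length, contributes
#'     an `(s, R^2)` pair. Binned means of `R^2` versus `s` are fitted by
#'     weighted least squares (Levenberg-Marquardt) to the planar law
#'     `<R^2(s)> = 4 Lp s - 8 Lp^2 (1 - exp(-s / (2 Lp)))`.}
#'   \item{`tangent_correlation`}{Tangent directions are estimated by chords
#'     spanning a `tangent_window` arc (suppressing the 45-degree lattice
#'     quantization of king-move chains); binned means of
#'     `<cos theta(s)>` are fitted on the log scale to `exp(-s / (2 Lp))` by
#'     weighted regression through the origin.}
#' }
#'
#' @param segments List of [segment] objects; a warning is issued below 20
#'   segments.
#' @param method `"end_to_end_fit"` (default) or `"tangent_correlation"`.
#' @param max_arc_fraction Largest arc separation used, as a fraction of each
#'   segment's contour length (default 0.5; longer separations on short
#'   segments are noisy and censored by junctions).
#' @param bin_width Arc-separation bin width in pixels (default 2).
#' @param tangent_window Chord length for tangent estimation in pixels
#'   (default 5; `tangent_correlation` only).
#' @return An object of class `lp_estimate`: list with `persistence_length`
#'   (pixels; `Inf` if non-estimable), `stderr`, `rmse`, `method`,
#'   `estimable`, `n_segments`, and the binned data in `bins`.
#' @export
estimate_persistence_length <- function(segments,
                                        method = c("end_to_end_fit",
                                                   "tangent_correlation"),
                                        max_arc_fraction = 0.5,
                                        bin_width = 2,
                                        tangent_window = 5) {
  method <- match.arg(method)
  if (!is.list(segments) || length(segments) == 0L) {
    stop_invalid("persistence length requires at least one segment")
  }
  assert_fraction(max_arc_fraction, "max_arc_fraction")
  assert_positive(bin_width, "bin_width")
  assert_positive(tangent_window, "tangent_window")
  if (length(segments) < 20L) {
    warning("fewer than 20 segments; persistence-length estimate will be noisy",
            call. = FALSE)
  }

  ## straight ensembles have no angular signal: flag non-estimable
  turn <- unlist(lapply(segments, function(sg) {
    d <- diff(sg$chain)
    diff(atan2(d[, 1L], d[, 2L]))
  }))
  if (length(turn) == 0L || stats::sd(cos(turn)) < 1e-12) {
    return(structure(list(persistence_length = Inf, stderr = NA_real_,
                          rmse = NA_real_, method = method, estimable = FALSE,
                          n_segments = length(segments), bins = NULL),
                     class = "lp_estimate"))
  }

  collect <- function(fun, ...) {
    parts <- lapply(segments, function(sg) fun(sg$chain, ...))
    list(s = unlist(lapply(parts, `[[`, "s")),
         v = unlist(lapply(parts, `[[`, "v")))
  }

  if (method == "end_to_end_fit") {
    pr <- collect(e2e_pairs, max_arc_fraction)
    bins <- bin_means(pr$s, pr$v, bin_width)
    bins <- bins[bins$s > 0, , drop = FALSE]
    if (nrow(bins) < 3L) stop_invalid("too few arc-separation bins for the fit")
    ## moment-based start: invert the ratio <R^2>/s^2 at the largest usable s
    lp0 <- max(bins$s) / 4
    fit <- tryCatch(
      minpack.lm::nlsLM(mean ~ wlc_r2(s, lp), data = bins,
                        start = list(lp = lp0),
                        lower = 1e-3, upper = 1e9,
                        weights = bins$n,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        stop_invalid("persistence-length fit did not converge: %s",
                     conditionMessage(e))
      })
    lp <- unname(stats::coef(fit)[["lp"]])
    se <- tryCatch(unname(summary(fit)$coefficients["lp", "Std. Error"]),
                   error = function(e) NA_real_)
    rmse <- sqrt(mean(stats::residuals(fit)^2))
  } else {
    pr <- collect(tangent_pairs, max_arc_fraction, tangent_window)
    bins <- bin_means(pr$s, pr$v, bin_width)
    bins <- bins[bins$mean > 0, , drop = FALSE]  # log scale needs positive means
    if (nrow(bins) < 3L) stop_invalid("too few arc-separation bins for the fit")
    fit <- stats::lm(log(mean) ~ 0 + s, data = bins, weights = bins$n)
    slope <- unname(stats::coef(fit)[["s"]])
    if (slope >= 0) {
      return(structure(list(persistence_length = Inf, stderr = NA_real_,
                            rmse = NA_real_, method = method, estimable = FALSE,
                            n_segments = length(segments), bins = bins),
                       class = "lp_estimate"))
    }
    lp <- -1 / (2 * slope)
    se_slope <- unname(summary(fit)$coefficients["s", "Std. Error"])
    se <- se_slope / (2 * slope^2)
    rmse <- sqrt(mean(stats::residuals(fit)^2))
  }
  structure(list(persistence_length = lp, stderr = se, rmse = rmse,
                 method = method, estimable = TRUE,
                 n_segments = length(segments), bins = bins),
            class = "lp_estimate")
}

#' @export
print.lp_estimate <- function(x, ...) {
  if (x$estimable) {
    cat(sprintf("<lp_estimate:%s> Lp = %.2f px (se %.2f, rmse %.3g) from %d segments\n",
                x$method, x$persistence_length, x$stderr, x$rmse, x$n_segments))
  } else {
    cat(sprintf("<lp_estimate:%s> non-estimable (straight segments) from %d segments\n",
                x$method, x$n_segments))
  }
  invisible(x)
}

#' Summarize the morphometry of one condition
#'
#' Pools all segments of one condition (typically all images of one specimen
#' group) and computes the full per-condition summary: segment count,
#' mean-squared end-to-end distance and contour length, bending ratio, and a
#' persistence-length estimate with fit diagnostics. Median segment length is
#' reported as a censoring diagnostic (junction density shortens segments; no
#' correction is applied).
#'
#' @param segments Non-empty list of [segment] objects.
#' @param pixel_scale Optional nm-per-pixel scale; when given, lengths are
#'   also reported in nanometers.
#' @param estimator Persistence-length estimator, see
#'   [estimate_persistence_length()].
#' @param bending_method Bending-ratio variant, see [bending_ratio()].
#' @param ... Further arguments passed to [estimate_persistence_length()].
#' @return An object of class `morphometry_result`.
#' @export
summarize_condition <- function(segments, pixel_scale = NULL,
                                estimator = c("end_to_end_fit",
                                              "tangent_correlation"),
                                bending_method = c("ratio_of_means",
                                                   "mean_of_ratios"),
                                ...) {
  estimator <- match.arg(estimator)
  br <- bending_ratio(segments, method = match.arg(bending_method))
  lp <- tryCatch(
    suppressWarnings(
      estimate_persistence_length(segments, method = estimator, ...)),
    error = function(e) {
      structure(list(persistence_length = NA_real_, stderr = NA_real_,
                     rmse = NA_real_, method = estimator, estimable = FALSE,
                     n_segments = length(segments), bins = NULL),
                class = "lp_estimate")
    })
  res <- list(
    n_segments = br$n_segments,
    mean_sq_end_to_end = br$mean_sq_end_to_end,
    mean_sq_contour = br$mean_sq_contour,
    bending_ratio = br$bending_ratio,
    persistence_length = lp$persistence_length,
    persistence_length_stderr = lp$stderr,
    estimator = lp$method,
    estimable = lp$estimable,
    fit_rmse = lp$rmse,
    median_segment_length = stats::median(
      vapply(segments, `[[`, numeric(1), "contour_length")),
    pixel_scale = pixel_scale
  )
  if (!is.null(pixel_scale)) {
    assert_positive(pixel_scale, "pixel_scale")
    res$persistence_length_nm <- res$persistence_length * pixel_scale
    res$median_segment_length_nm <- res$median_segment_length * pixel_scale
  }
  structure(res, class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf("<morphometry_result> %d segments\n", x$n_segments))
  cat(sprintf("  bending ratio      %.4f\n", x$bending_ratio))
  if (is.finite(x$persistence_length)) {
    cat(sprintf("  persistence length %.2f px (se %.2f, %s)\n",
                x$persistence_length, x$persistence_length_stderr,
                x$estimator))
    if (!is.null(x$persistence_length_nm)) {
      cat(sprintf("                     %.1f nm at %g nm/px\n",
                  x$persistence_length_nm, x$pixel_scale))
    }
  } else {
    cat(sprintf("  persistence length non-estimable (%s)\n", x$estimator))
  }
  cat(sprintf("  median segment length %.1f px\n", x$median_segment_length))
  invisible(x)
}
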