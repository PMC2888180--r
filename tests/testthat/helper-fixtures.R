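# Fixtures are built in code: small hand-enumerable skeleton masks, worm-like
# chain ensembles, and an exhaustive Mann-Whitney oracle.

plus_mask <- function() {
  m <- matrix(FALSE, 11, 11)
  m[6, 2:10] <- TRUE
  m[2:10, 6] <- TRUE
  m
}

line_mask <- function(n = 10) {
  m <- matrix(FALSE, 11, n + 4)
  m[5, 3:(n + 2)] <- TRUE
  m
}

## 20-px horizontal bar with a 2-px stem hanging from its center
t_with_spur_mask <- function() {
  m <- matrix(FALSE, 15, 26)
  m[5, 3:22] <- TRUE
  m[6:7, 12] <- TRUE
  m
}

## square 1-px ring (closed loop, no endpoints or junctions)
ring_mask <- function() {
  m <- matrix(FALSE, 12, 12)
  m[4:9, 4] <- TRUE; m[4:9, 9] <- TRUE
  m[4, 4:9] <- TRUE; m[9, 4:9] <- TRUE
  m
}

## ensemble of worm-like-chain segments with random initial directions
wlc_segments <- function(n, contour, lp, step = 1) {
  lapply(seq_len(n), function(i) {
    p <- sample_wlc_path(c(0, 0), stats::runif(1, 0, 2 * pi),
                         total_length = contour, persistence_length = lp,
                         step_length = step)
    segment(p$points)
  })
}

## a small, fast synthetic spec for unit tests (256 px canvas, one fibril
## scale down from the 512 px defaults)
small_spec <- function(n_fibrils = 2, fibril_length = 90, ...) {
  synthetic_image_spec(image_height = 256, image_width = 256,
                       n_fibrils = n_fibrils, fibril_length = fibril_length,
                       ...)
}

## exhaustive Mann-Whitney oracle: enumerate every assignment of the pooled
## observations to group A, compute the U distribution, and return the exact
## two-sided p for the observed U (independent of wilcox.test)
mw_enumeration_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(length(pooled), na)
  u_all <- apply(combos, 2, function(ix) {
    sum(r[ix]) - na * (na + 1) / 2
  })
  mu <- na * length(b) / 2
  p <- if (u_obs >= mu) {
    2 * mean(u_all >= u_obs)
  } else {
    2 * mean(u_all <= u_obs)
  }
  min(1, p)
}

## max over chain points of the min distance to a reference polyline's points
max_min_dist <- function(chain, pts) {
  max(apply(chain, 1, function(q) {
    sqrt(min((pts[, 1] - q[1])^2 + (pts[, 2] - q[2])^2))
  }))
}
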