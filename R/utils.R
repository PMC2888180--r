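#' @keywords internal
"_PACKAGE"

## internal validation helpers ------------------------------------------------

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (allow_inf || is.finite(x)) && x >= lower && x <= upper
  if (!ok) {
    stop_invalid("`%s` must be a single number in [%s, %s] (got %s)",
                 name, format(lower), format(upper),
                 paste(format(x), collapse = ", "))
  }
  invisible(x)
}

assert_positive <- function(x, name, allow_inf = FALSE) {
  assert_number(x, name, allow_inf = allow_inf)
  if (x <= 0) stop_invalid("`%s` must be > 0 (got %s)", name, format(x))
  invisible(x)
}

assert_fraction <- function(x, name) {
  assert_number(x, name, lower = 0, upper = 1)
}

#' Derive a stage-specific random seed from a global seed
#'
#' A single global seed feeds every stage of the pipeline through
#' stage-name-salted derived seeds, so that adding or reordering stages never
#' perturbs the random stream of the others. The derivation is a simple
#' deterministic integer hash of the stage label folded into the seed, reduced
#' modulo 2^31 - 1.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label (e.g. `"simulate/healthy"`).
#' @return A single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1L, "simulate")
#' derive_seed(1L, "extract")
derive_seed <- function(seed, stage) {
  assert_number(seed, "seed")
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(stage)) {
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer(h)
}

## matrix shift with zero padding; dr > 0 shifts content down, dc > 0 right.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

## 8-neighborhood offsets (row, col)
NEIGHBOR_OFFSETS <- cbind(
  dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
  dc = c(-1,  0,  1, -1, 1, -1, 0, 1)
)

## Label 8-connected components of a logical matrix. Returns an integer matrix
## (0 = background). EBImage::bwlabel is 4-connected, hence igraph here.
label_components8 <- function(mask) {
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0L) return(lab)
  nr <- nrow(mask)
  pos <- integer(length(mask))
  pos[idx] <- seq_along(idx)
  edges <- vector("list", 4L)
  ## half of the 8 offsets suffices for an undirected graph
  half <- NEIGHBOR_OFFSETS[c(1L, 2L, 3L, 5L), , drop = FALSE]
  r <- ((idx - 1L) %% nr) + 1L
  co <- ((idx - 1L) %/% nr) + 1L
  for (k in seq_len(nrow(half))) {
    rr <- r + half[k, 1L]; cc <- co + half[k, 2L]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= ncol(mask)
    nb <- (cc[ok] - 1L) * nr + rr[ok]
    keep <- mask[nb]
    edges[[k]] <- rbind(pos[idx[ok]][keep], pos[nb][keep])
  }
  el <- do.call(cbind, edges)
  if (is.null(el) || ncol(el) == 0L) {
    lab[idx] <- seq_along(idx)
    return(lab)
  }
  g <- igraph::graph_from_edgelist(t(el), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}
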