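#' Skeleton graph of endpoints, junctions and pixel chains
#'
#' [build_skeleton_graph()] decomposes a one-pixel-wide skeleton into a graph.
#' A pixel with exactly one 8-neighbor on the skeleton is an endpoint; a pixel
#' whose crossing number (the number of distinct foreground runs around its
#' 8-neighborhood ring, which equals the number of incident chains) is 3 or
#' more is a junction. Junction pixels that are mutually 8-adjacent are merged
#' into a single junction node (thinning can emit small junction clusters, and
#' merging stabilizes junction counts). Chains are the
#' ordered 8-connected pixel runs joining two node pixels; an isolated closed
#' loop with no endpoint or junction receives a single `cycle-anchor` node and
#' one chain that returns to it. Isolated single pixels are discarded.
#'
#' Coordinates are 0-based `(row, col)` pixel positions; chain contour
#' positions are measured between pixel centers, so each step is 1 or
#' `sqrt(2)` pixels long.
#'
#' @param skeleton A [binary_image] with provenance `"skeleton"`, or a logical
#'   matrix that is already one pixel wide.
#' @return An object of class `skeleton_graph`: a list with
#'   \describe{
#'     \item{nodes}{data.frame with `node_id`, `row`, `col` (cluster centroid,
#'       0-based), `kind` (`"endpoint"`, `"junction"`, `"cycle-anchor"`) and
#'       `n_pixels` (cluster size).}
#'     \item{chains}{list of integer matrices (columns `row`, `col`, 0-based),
#'       each chain including its terminal node pixels.}
#'     \item{chain_info}{data.frame with `chain_id`, `from_node`, `to_node`,
#'       `n_points`, `contour_length`.}
#'     \item{dim}{dimensions of the source mask.}
#'   }
#' @export
#' @examples
#' plus <- matrix(FALSE, 11, 11)
#' plus[6, 2:10] <- TRUE; plus[2:10, 6] <- TRUE
#' g <- build_skeleton_graph(binary_image(plus, "skeleton"))
#' table(g$nodes$kind)
build_skeleton_graph <- function(skeleton) {
  skel <- unclass(as.matrix(skeleton)) > 0
  nr <- nrow(skel); nc <- ncol(skel)

  cnt <- matrix(0L, nr, nc)
  for (k in seq_len(nrow(NEIGHBOR_OFFSETS))) {
    cnt <- cnt + shift_mat(skel * 1L, NEIGHBOR_OFFSETS[k, 1L],
                           NEIGHBOR_OFFSETS[k, 2L])
  }
  cnt[!skel] <- 0L

  ## crossing number: foreground runs around the 8-ring (N, NE, E, SE, S, SW,
  ## W, NW). A raw neighbor count over-classifies pixels next to a crossing
  ## (their neighbors are mutually adjacent); the run count equals the number
  ## of incident chains.
  ring <- list(c(1, 0), c(1, -1), c(0, -1), c(-1, -1),
               c(-1, 0), c(-1, 1), c(0, 1), c(1, 1))
  rv <- lapply(ring, function(o) shift_mat(skel * 1L, o[1L], o[2L]))
  runs <- matrix(0L, nr, nc)
  for (k in seq_along(rv)) {
    nxt <- rv[[if (k == length(rv)) 1L else k + 1L]]
    runs <- runs + (rv[[k]] == 0L & nxt == 1L)
  }

  junction_px <- skel & runs >= 3L
  endpoint_px <- skel & cnt == 1L

  ## node ids: junction clusters first, then endpoints
  jlab <- label_components8(junction_px)
  n_junctions <- max(jlab)
  node_of <- jlab
  ep_idx <- which(endpoint_px)
  node_of[ep_idx] <- n_junctions + seq_along(ep_idx)
  n_nodes <- n_junctions + length(ep_idx)

  nodes <- data.frame(node_id = seq_len(n_nodes),
                      row = rep(NA_real_, n_nodes),
                      col = rep(NA_real_, n_nodes),
                      kind = rep(c("junction", "endpoint"),
                                 c(n_junctions, length(ep_idx))),
                      n_pixels = rep(0L, n_nodes),
                      stringsAsFactors = FALSE)
  node_px_idx <- which(node_of > 0L)
  if (length(node_px_idx)) {
    nid <- node_of[node_px_idx]
    r0 <- ((node_px_idx - 1L) %% nr)        # 0-based
    c0 <- ((node_px_idx - 1L) %/% nr)
    nodes$row <- as.numeric(tapply(r0, nid, mean)[as.character(seq_len(n_nodes))])
    nodes$col <- as.numeric(tapply(c0, nid, mean)[as.character(seq_len(n_nodes))])
    nodes$n_pixels <- tabulate(nid, n_nodes)
  }

  neighbors_of <- function(i) {
    r <- ((i - 1L) %% nr) + 1L
    co <- ((i - 1L) %/% nr) + 1L
    rr <- r + NEIGHBOR_OFFSETS[, 1L]
    cc <- co + NEIGHBOR_OFFSETS[, 2L]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    nb <- (cc[ok] - 1L) * nr + rr[ok]
    nb[skel[nb]]
  }

  visited <- matrix(FALSE, nr, nc)
  chains <- list()
  from_node <- integer(); to_node <- integer()

  emit <- function(ix, from, to) {
    chains[[length(chains) + 1L]] <<- ix
    from_node[length(from_node) + 1L] <<- from
    to_node[length(to_node) + 1L] <<- to
  }

  trace_from <- function(np, nb) {
    chain <- c(np, nb)
    visited[nb] <<- TRUE
    prev <- np; cur <- nb
    repeat {
      nbrs <- neighbors_of(cur)
      nbrs <- nbrs[nbrs != prev]
      node_nbrs <- nbrs[node_of[nbrs] > 0L]
      if (length(node_nbrs)) {
        term <- node_nbrs[1L]
        chain <- c(chain, term)
        return(list(chain = chain, to = node_of[term]))
      }
      nxt <- nbrs[!visited[nbrs]]
      if (length(nxt) == 0L) {
        return(list(chain = chain, to = 0L))  # dead end (should not occur)
      }
      if (length(nxt) > 1L) {
        ## near a junction or corner, chain pixels can be mutually adjacent;
        ## stepping to a pixel that also touches `prev`, or diagonally when an
        ## orthogonal step exists, would cut the corner
        pr <- abs(((nxt - 1L) %% nr) - ((prev - 1L) %% nr)) <= 1L &
              abs(((nxt - 1L) %/% nr) - ((prev - 1L) %/% nr)) <= 1L
        if (any(!pr)) nxt <- nxt[!pr]
        diag <- ((nxt - 1L) %% nr) != ((cur - 1L) %% nr) &
                ((nxt - 1L) %/% nr) != ((cur - 1L) %/% nr)
        if (any(!diag)) nxt <- nxt[!diag]
      }
      nxt <- nxt[1L]
      chain <- c(chain, nxt)
      visited[nxt] <<- TRUE
      prev <- cur; cur <- nxt
    }
  }

  for (np in node_px_idx) {
    this_node <- node_of[np]
    for (nb in neighbors_of(np)) {
      nb_node <- node_of[nb]
      if (nb_node > 0L) {
        ## direct node-node adjacency: intra-cluster links are not chains
        if (nb_node != this_node && np < nb) emit(c(np, nb), this_node, nb_node)
      } else if (!visited[nb]) {
        tr <- trace_from(np, nb)
        ## discard 3-pixel cluster self-links (adjacency redundancy around a
        ## junction cluster), keep genuine loops
        if (!(tr$to == this_node && length(tr$chain) <= 3L)) {
          emit(tr$chain, this_node, tr$to)
        }
      }
    }
  }

  ## isolated closed loops: degree-2 pixels never visited and not nodes
  loop_left <- which(skel & !visited & node_of == 0L & cnt == 2L)
  for (anchor in loop_left) {
    if (visited[anchor]) next
    visited[anchor] <- TRUE
    nbrs <- neighbors_of(anchor)
    node_of[anchor] <- n_nodes + 1L
    n_nodes <- n_nodes + 1L
    nodes <- rbind(nodes, data.frame(
      node_id = n_nodes,
      row = (anchor - 1L) %% nr, col = (anchor - 1L) %/% nr,
      kind = "cycle-anchor", n_pixels = 1L, stringsAsFactors = FALSE))
    tr <- trace_from(anchor, nbrs[1L])
    emit(tr$chain, node_of[anchor], node_of[anchor])
  }

  chain_mats <- lapply(chains, function(ix) {
    cbind(row = (ix - 1L) %% nr, col = (ix - 1L) %/% nr)
  })
  clen <- vapply(chain_mats, function(m) {
    if (nrow(m) < 2L) 0 else sum(sqrt(rowSums(diff(m)^2)))
  }, numeric(1))
  chain_info <- data.frame(chain_id = seq_along(chain_mats),
                           from_node = from_node, to_node = to_node,
                           n_points = vapply(chain_mats, nrow, integer(1)),
                           contour_length = clen)
  structure(list(nodes = nodes, chains = chain_mats,
                 chain_info = chain_info, dim = c(nr, nc)),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  k <- table(factor(x$nodes$kind,
                    levels = c("endpoint", "junction", "cycle-anchor")))
  cat(sprintf(
    "<skeleton_graph> %d endpoints, %d junctions, %d cycle anchors, %d chains\n",
    k[["endpoint"]], k[["junction"]], k[["cycle-anchor"]],
    length(x$chains)))
  invisible(x)
}

## drop chains by index, keeping nodes (used by pruning/filtering)
drop_chains <- function(graph, drop) {
  if (length(drop) == 0L) return(graph)
  keep <- setdiff(seq_along(graph$chains), drop)
  graph$chains <- graph$chains[keep]
  graph$chain_info <- graph$chain_info[graph$chain_info$chain_id %in% keep, ,
                                       drop = FALSE]
  graph$chain_info$chain_id <- seq_along(graph$chains)
  rownames(graph$chain_info) <- NULL
  graph
}

#' Prune short spur chains from a skeleton graph
#'
#' A spur is an endpoint-to-junction chain, typically a thinning artifact at
#' fibril ends or crossings. Chains from an endpoint to a junction with
#' contour length strictly below `min_length` are removed, along with their
#' endpoint node. Surviving chains are not re-merged across the junction.
#'
#' @param graph A `skeleton_graph`.
#' @param min_length Pruning threshold in pixels (0 disables).
#' @return The pruned `skeleton_graph`.
#' @export
prune_spurs <- function(graph, min_length = 5) {
  assert_number(min_length, "min_length", lower = 0)
  if (min_length == 0) return(graph)
  kind <- graph$nodes$kind
  ci <- graph$chain_info
  ## node id 0 marks a dangling chain end; never index kind with it
  kf <- rep(NA_character_, nrow(ci))
  kt <- rep(NA_character_, nrow(ci))
  kf[ci$from_node > 0L] <- kind[ci$from_node[ci$from_node > 0L]]
  kt[ci$to_node > 0L] <- kind[ci$to_node[ci$to_node > 0L]]
  is_spur <- !is.na(kf) & !is.na(kt) &
    ((kf == "endpoint" & kt == "junction") |
       (kf == "junction" & kt == "endpoint"))
  drop <- ci$chain_id[is_spur & ci$contour_length < min_length]
  g <- drop_chains(graph, drop)
  used <- unique(c(g$chain_info$from_node, g$chain_info$to_node))
  g$nodes <- g$nodes[g$nodes$node_id %in% used | g$nodes$kind == "junction", ,
                     drop = FALSE]
  g
}

#' Extract measurable line segments from a skeleton graph
#'
#' Applies spur pruning, then emits every surviving chain whose contour length
#' is at least `min_segment_length` as a [segment] carrying its ordered pixel
#' chain, contour length and end-to-end distance.
#'
#' @param graph A `skeleton_graph`.
#' @param min_segment_length Minimum contour length (pixels) of emitted
#'   segments; shorter chains are excluded.
#' @param prune_spurs_shorter_than Spur-pruning threshold passed to
#'   [prune_spurs()].
#' @return A list of [segment] objects (possibly empty).
#' @export
extract_segments <- function(graph, min_segment_length = 10,
                             prune_spurs_shorter_than = 5) {
  stopifnot(inherits(graph, "skeleton_graph"))
  assert_number(min_segment_length, "min_segment_length", lower = 0)
  g <- prune_spurs(graph, prune_spurs_shorter_than)
  keep <- g$chain_info$contour_length >= min_segment_length &
    g$chain_info$n_points >= 2L
  lapply(g$chains[keep], segment)
}
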