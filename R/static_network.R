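#' Default 25-node static layout
#'
#' Places 25 static nodes uniformly over the arena: 1 at the centre, 8
#' equally spaced on a ring of radius `arena_radius / 2`, and 16 equally
#' spaced on a ring of radius `0.85 * arena_radius` (both rings starting at
#' the canonical 45-degree angle, so the outer ring resolves all 12 holes).
#' Each node's zone is the set of arena points nearest to it (a Voronoi
#' cell clipped to the disk), and two zones are "allowed" neighbours when
#' their cells share a boundary.  Zone adjacency is derived from a fine
#' raster of the arena disk (step `grid_px`): two zones are adjacent when
#' some pair of 4-neighbouring raster cells belongs to one each.
#'
#' @param spec an [arena_spec()].
#' @param grid_px raster step (pixels) used to derive zone adjacency.
#' @param nodes optional `25 x 2` matrix overriding the node coordinates
#'   (e.g. read from a layout JSON).
#' @return An object of class `static_layout`: list with `nodes`
#'   (data.frame `id`, `x`, `y`), `adjacency_allowed` (symmetric logical
#'   matrix, zero diagonal), `grid_px`.
#' @export
default_static_layout <- function(spec, grid_px = 2, nodes = NULL) {
  stopifnot(inherits(spec, "arena_spec"), grid_px > 0)
  if (is.null(nodes)) {
    a8 <- pi / 4 + (0:7) * 2 * pi / 8
    a16 <- pi / 4 + (0:15) * 2 * pi / 16
    nodes <- rbind(
      matrix(spec$center, 1),
      arena_point(a8, spec$arena_radius / 2, spec),
      arena_point(a16, 0.85 * spec$arena_radius, spec)
    )
  } else {
    nodes <- matrix(as.numeric(nodes), ncol = 2)
  }
  k <- nrow(nodes)
  gx <- seq(spec$center[1] - spec$arena_radius,
            spec$center[1] + spec$arena_radius, by = grid_px)
  gy <- seq(spec$center[2] - spec$arena_radius,
            spec$center[2] + spec$arena_radius, by = grid_px)
  grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  inside <- arena_dist(grid, spec) <= spec$arena_radius
  lab <- matrix(NA_integer_, length(gx), length(gy))
  lab[inside] <- nearest_node_id(grid[inside, , drop = FALSE], nodes)
  allowed <- matrix(FALSE, k, k)
  h1 <- lab[-nrow(lab), ]
  h2 <- lab[-1, ]
  v1 <- lab[, -ncol(lab)]
  v2 <- lab[, -1]
  pairs <- rbind(cbind(as.vector(h1), as.vector(h2)),
                 cbind(as.vector(v1), as.vector(v2)))
  pairs <- pairs[stats::complete.cases(pairs) & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  allowed[pairs] <- TRUE
  allowed <- allowed | t(allowed)
  structure(list(
    nodes = data.frame(id = seq_len(k), x = nodes[, 1], y = nodes[, 2]),
    adjacency_allowed = allowed,
    grid_px = grid_px
  ), class = "static_layout")
}

#' @export
print.static_layout <- function(x, ...) {
  cat(sprintf("<static_layout> %d nodes, %d allowed neighbour pairs\n",
              nrow(x$nodes), sum(x$adjacency_allowed) / 2))
  invisible(x)
}

# 1-based id of the nearest node for each point; ties to the lowest id
nearest_node_id <- function(points, nodes) {
  points <- matrix(points, ncol = 2)
  d2 <- outer(points[, 1], nodes[, 1], "-")^2 +
    outer(points[, 2], nodes[, 2], "-")^2
  max.col(-d2, ties.method = "first")
}

#' Per-frame static node sequence
#'
#' Converts a trajectory to the sequence of nearest static nodes (Euclidean
#' distance, ties to the lowest node id).
#'
#' @param traj a [trajectory()] in the canonical frame.
#' @param layout a [default_static_layout()].
#' @return integer vector of node ids (1-based), one per frame.
#' @export
node_sequence <- function(traj, layout) {
  stopifnot(inherits(traj, "maz_trajectory"), inherits(layout, "static_layout"))
  nearest_node_id(traj_xy(traj), cbind(layout$nodes$x, layout$nodes$y))
}

# ordered chain of distinct zone ids crossed by the straight segment p->q,
# refined until every consecutive pair is an allowed neighbour
segment_zone_chain <- function(p, q, layout) {
  nodes <- cbind(layout$nodes$x, layout$nodes$y)
  len <- sqrt(sum((q - p)^2))
  step <- max(2L, ceiling(len / (layout$grid_px / 2)) + 1L)
  for (refine in 1:3) {
    tt <- seq(0, 1, length.out = step)
    pts <- cbind(p[1] + tt * (q[1] - p[1]), p[2] + tt * (q[2] - p[2]))
    ids <- nearest_node_id(pts, nodes)
    ids <- ids[c(TRUE, diff(ids) != 0)]
    ok <- length(ids) < 2 ||
      all(layout$adjacency_allowed[cbind(ids[-length(ids)], ids[-1])])
    if (ok) return(ids)
    step <- step * 4L
  }
  ids
}

#' Build the per-trial static (zone) network
#'
#' Links are added for transitions between consecutive distinct zones in
#' the per-frame node sequence.  When the two zones are allowed neighbours
#' the link is added directly; otherwise (a between-frame jump across
#' intermediate zones) the straight segment between the two frame positions
#' is decomposed into the ordered chain of zones it crosses and a link is
#' added for every consecutive pair along the chain, preserving planarity
#' (`adjacency <= adjacency_allowed` elementwise).  Self-transitions are
#' ignored.
#'
#' @param node_seq integer vector from [node_sequence()].
#' @param layout the [default_static_layout()] that produced it.
#' @param positions optional `n x 2` matrix of the frame positions behind
#'   `node_seq`, used for segment decomposition of non-adjacent jumps;
#'   without it the segment between the two node centroids is used.
#' @return A `behavior_network` of kind `"static"`.  Node ids refer to the
#'   layout; only visited zones become nodes.
#' @export
build_static_network <- function(node_seq, layout, positions = NULL) {
  stopifnot(length(node_seq) >= 1, inherits(layout, "static_layout"))
  k <- nrow(layout$nodes)
  A <- matrix(0, k, k)
  counts <- matrix(0, k, k)
  visited <- logical(k)
  visited[node_seq[1]] <- TRUE
  if (length(node_seq) > 1) {
    for (i in seq_len(length(node_seq) - 1L)) {
      u <- node_seq[i]
      v <- node_seq[i + 1L]
      visited[v] <- TRUE
      if (u == v) next
      if (layout$adjacency_allowed[u, v]) {
        chain <- c(u, v)
      } else {
        if (!is.null(positions)) {
          p <- positions[i, ]
          q <- positions[i + 1L, ]
        } else {
          p <- c(layout$nodes$x[u], layout$nodes$y[u])
          q <- c(layout$nodes$x[v], layout$nodes$y[v])
        }
        chain <- segment_zone_chain(as.numeric(p), as.numeric(q), layout)
        if (chain[1] != u) chain <- c(u, chain)
        if (chain[length(chain)] != v) chain <- c(chain, v)
        visited[chain] <- TRUE
      }
      for (j in seq_len(length(chain) - 1L)) {
        a <- chain[j]
        b <- chain[j + 1L]
        if (a == b || !layout$adjacency_allowed[a, b]) next
        A[a, b] <- A[b, a] <- 1
        counts[a, b] <- counts[b, a] <- counts[a, b] + 1
      }
    }
  }
  idx <- which(visited)
  nodes <- data.frame(id = idx, x = layout$nodes$x[idx],
                      y = layout$nodes$y[idx],
                      n_members = as.integer(tabulate(node_seq, k)[idx]))
  behavior_network(nodes, A[idx, idx, drop = FALSE],
                   counts[idx, idx, drop = FALSE], "static",
                   layout_ids = idx)
}
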