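#' Detect stop episodes
#'
#' A sliding window of `stop_window` frames qualifies as stopped when the
#' path length travelled within it (sum of inter-frame step norms) is below
#' `stop_threshold`.  Overlapping qualifying windows are merged into maximal
#' runs, each yielding one stop episode summarised by the centroid of all
#' its frames; a long pause therefore produces a single stop rather than a
#' near-duplicate stop per window.
#'
#' @param traj a [trajectory()].
#' @param spec an [arena_spec()] providing `stop_threshold` (px) and
#'   `stop_window` (frames).
#' @return data.frame of class `stop_episodes`, one row per episode:
#'   `start_frame`, `end_frame` (1-based, inclusive; span >= `stop_window`),
#'   `x`, `y` (centroid).  Ordered and non-overlapping; empty for
#'   trajectories shorter than the window.
#' @export
detect_stops <- function(traj, spec) {
  stopifnot(inherits(traj, "maz_trajectory"), inherits(spec, "arena_spec"))
  nf <- n_frames(traj)
  w <- spec$stop_window
  empty <- data.frame(start_frame = integer(0), end_frame = integer(0),
                      x = numeric(0), y = numeric(0))
  class(empty) <- c("stop_episodes", "data.frame")
  if (nf < w) return(empty)
  steps <- sqrt(diff(traj$frames$x)^2 + diff(traj$frames$y)^2)
  cs <- c(0, cumsum(steps))
  # path length of window starting at frame i: frames i .. i + w - 1
  win_len <- cs[w:nf] - cs[seq_len(nf - w + 1)]
  qual <- win_len < spec$stop_threshold
  stopped <- logical(nf)
  qi <- which(qual)
  for (i in qi) stopped[i:(i + w - 1L)] <- TRUE
  r <- rle(stopped)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(
    start_frame = starts[keep], end_frame = ends[keep],
    x = vapply(keep, function(k) {
      mean(traj$frames$x[starts[k]:ends[k]])
    }, numeric(1)),
    y = vapply(keep, function(k) {
      mean(traj$frames$y[starts[k]:ends[k]])
    }, numeric(1))
  )
  class(out) <- c("stop_episodes", "data.frame")
  out
}

#' City Clustering Algorithm
#'
#' Iterative nearest-node agglomeration of 2-D points.  Each pass visits the
#' points in their given (chronological) order: a point joins the nearest
#' existing node if it lies within `threshold` of its centroid, otherwise it
#' spawns a new node at its own position.  After every pass node centroids
#' are recomputed as the means of their members and empty nodes are dropped;
#' passes repeat until the point-to-node partition is unchanged (or
#' `max_iter` passes, reported via the `converged` flag).  For
#' well-separated point groups the resulting partition is independent of
#' the processing order.
#'
#' @param points numeric `m x 2` matrix of points (rows in chronological
#'   order).
#' @param threshold integration distance, pixels.
#' @param max_iter maximum number of refinement passes.
#' @return list with `centroids` (`k x 2` matrix), `assignment` (length-`m`
#'   integer vector of node ids, 1-based, numbered by first appearance),
#'   `converged`, `iterations`.
#' @export
cca_cluster <- function(points, threshold, max_iter = 100L) {
  points <- matrix(as.numeric(points), ncol = 2)
  m <- nrow(points)
  if (m == 0) stop("cca_cluster needs at least one point")
  stopifnot(threshold > 0, all(is.finite(points)))
  cent <- NULL
  prev_part <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    cur <- cent # centroids carried over from the previous pass
    assign <- integer(m)
    for (p in seq_len(m)) {
      if (!is.null(cur) && nrow(cur) > 0) {
        d2 <- (cur[, 1] - points[p, 1])^2 + (cur[, 2] - points[p, 2])^2
        j <- which.min(d2)
        if (sqrt(d2[j]) < threshold) {
          assign[p] <- j
          next
        }
      }
      cur <- rbind(cur, points[p, , drop = FALSE])
      assign[p] <- nrow(cur)
    }
    # relabel by first appearance (also drops nodes that lost all members)
    part <- match(assign, unique(assign))
    k <- max(part)
    cent <- matrix(0, k, 2)
    for (g in seq_len(k)) {
      idx <- part == g
      cent[g, ] <- c(mean(points[idx, 1]), mean(points[idx, 2]))
    }
    if (!is.null(prev_part) && identical(part, prev_part)) {
      converged <- TRUE
      break
    }
    prev_part <- part
  }
  if (!converged) {
    warning("CCA did not converge within ", max_iter, " passes")
  }
  list(centroids = cent, assignment = prev_part, converged = converged,
       iterations = iter)
}

#' Behaviour network constructor
#'
#' @param nodes data.frame with columns `id`, `x`, `y`, `n_members`.
#' @param adjacency symmetric binary matrix with zero diagonal.
#' @param counts symmetric transition-count matrix (positive exactly where
#'   `adjacency` is 1).
#' @param kind `"dynamic"`, `"static"` or `"global"`.
#' @param ... further fields stored on the object (e.g. `members`,
#'   `n_stops`).
#' @return object of class `behavior_network`.
#' @keywords internal
behavior_network <- function(nodes, adjacency, counts, kind, ...) {
  n <- nrow(nodes)
  stopifnot(nrow(adjacency) == n, ncol(adjacency) == n,
            identical(dim(adjacency), dim(counts)))
  if (n > 0) {
    stopifnot(all(adjacency == t(adjacency)), all(diag(adjacency) == 0),
              all((counts > 0) == (adjacency == 1)))
  }
  structure(
    c(list(nodes = nodes, adjacency = adjacency, counts = counts,
           kind = kind), list(...)),
    class = "behavior_network"
  )
}

#' @export
print.behavior_network <- function(x, ...) {
  m <- sum(x$adjacency) / 2
  cat(sprintf("<behavior_network:%s> order %d, %d links\n",
              x$kind, nrow(x$nodes), m))
  invisible(x)
}

empty_network <- function(kind, ...) {
  behavior_network(
    nodes = data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                       n_members = integer(0)),
    adjacency = matrix(0, 0, 0), counts = matrix(0, 0, 0), kind = kind, ...
  )
}

#' Build the per-trial dynamic (local) network
#'
#' Clusters the stop centroids of one trial into nodes with the City
#' Clustering Algorithm at `cca_threshold`, then links every pair of nodes
#' visited by consecutive stops: for successive stops mapped to nodes
#' `(u, v)` with `u != v`, the undirected link u-v is present and its
#' transition count incremented; stop pairs within the same node are
#' ignored (no self-links).  Link presence is binary for feature
#' computation; multiplicities are retained in `counts` for visualisation.
#'
#' @param stops a `stop_episodes` data.frame from [detect_stops()].
#' @param spec an [arena_spec()].
#' @return A `behavior_network` of kind `"dynamic"` with fields `members`
#'   (list of stop indices per node) and `n_stops`.  Zero stops give an
#'   order-0 network whose features are undefined downstream.
#' @export
build_local_network <- function(stops, spec) {
  stopifnot(is.data.frame(stops), inherits(spec, "arena_spec"))
  ns <- nrow(stops)
  if (ns == 0) {
    return(empty_network("dynamic", members = list(), n_stops = 0L))
  }
  cl <- cca_cluster(cbind(stops$x, stops$y), spec$cca_threshold)
  k <- nrow(cl$centroids)
  A <- matrix(0, k, k)
  counts <- matrix(0, k, k)
  if (ns > 1) {
    for (i in seq_len(ns - 1)) {
      u <- cl$assignment[i]
      v <- cl$assignment[i + 1]
      if (u != v) {
        A[u, v] <- A[v, u] <- 1
        counts[u, v] <- counts[v, u] <- counts[u, v] + 1
      }
    }
  }
  nodes <- data.frame(
    id = seq_len(k), x = cl$centroids[, 1], y = cl$centroids[, 2],
    n_members = as.integer(tabulate(cl$assignment, k))
  )
  behavior_network(nodes, A, counts, "dynamic",
                   members = split(seq_len(ns), cl$assignment),
                   n_stops = ns)
}
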