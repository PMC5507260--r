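#' @name network-features
#' @title Graph features of behaviour networks
#'
#' @description
#' The eight features characterising a trial's behaviour network, computed
#' on the binary, undirected, self-loop-free adjacency matrix:
#' number of stops `o`, order `n` (node count), degree `m/n` (links per
#' node, where `m = sum(A)/2` is the link count; note this is half the
#' conventional mean degree), density `2m / (n (n - 1))`, clustering
#' coefficient `C_ws` (redundancy form, see [net_clustering()]), mean
#' shortest path length `l`, mean betweenness centrality `x`, and mean
#' closeness centrality `cl`.
#'
#' Degenerate networks propagate `NA` ("undefined") rather than zeros, so
#' that group statistics can exclude them: density, clustering, shortest
#' path and closeness are undefined on networks too small or too
#' disconnected to support them.
#'
#' @param net a `behavior_network`, or a square adjacency matrix.
NULL

as_adjacency <- function(net) {
  if (inherits(net, "behavior_network")) {
    return(net$adjacency)
  }
  A <- as.matrix(net)
  stopifnot(nrow(A) == ncol(A))
  if (nrow(A) > 0) {
    stopifnot(all(A %in% c(0, 1)), all(A == t(A)), all(diag(A) == 0))
  }
  A
}

#' Link count m
#' @rdname network-features
#' @return `net_links`: integer `m = sum(A) / 2`.
#' @export
net_links <- function(net) {
  A <- as_adjacency(net)
  as.integer(round(sum(A) / 2))
}

#' Degree feature m/n
#' @rdname network-features
#' @return `net_degree`: links per node `m / n` (`NA` for an empty network).
#' @export
net_degree <- function(net) {
  A <- as_adjacency(net)
  n <- nrow(A)
  if (n == 0) return(NA_real_)
  net_links(A) / n
}

#' Density
#' @rdname network-features
#' @return `net_density`: `2m / (n (n - 1))`; `NA` when `n < 2`.
#' @export
net_density <- function(net) {
  A <- as_adjacency(net)
  n <- nrow(A)
  if (n < 2) return(NA_real_)
  2 * net_links(A) / (n * (n - 1))
}

#' Clustering coefficient (redundancy form)
#'
#' For each node `i` with degree `k_i >= 2`, the redundancy `R_i` is the
#' average number of links from a neighbour of `i` to the other neighbours
#' of `i`, and the local coefficient is `C_i = R_i / (k_i - 1)`
#' (algebraically equal to the usual triangles-over-pairs form).  The
#' network value is the mean of `C_i` over qualifying nodes; nodes with
#' fewer than two neighbours are excluded, and if no node qualifies the
#' feature is undefined.
#'
#' @rdname network-features
#' @export
net_clustering <- function(net) {
  A <- as_adjacency(net)
  n <- nrow(A)
  deg <- rowSums(A)
  idx <- which(deg >= 2)
  if (length(idx) == 0) return(NA_real_)
  ci <- vapply(idx, function(i) {
    nb <- which(A[i, ] == 1)
    # links among the neighbours of i, counted from each neighbour's side
    r_i <- sum(A[nb, nb]) / deg[i]
    r_i / (deg[i] - 1)
  }, numeric(1))
  mean(ci)
}

# all-pairs unweighted shortest-path lengths by BFS; Inf when unreachable
bfs_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  nbrs <- lapply(seq_len(n), function(i) which(A[i, ] == 1))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- unique(unlist(nbrs[frontier]))
      nxt <- nxt[dist[nxt] == Inf]
      dist[nxt] <- d
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

#' Mean shortest path length
#'
#' Mean number of links along the shortest path, over unordered pairs of
#' distinct mutually reachable nodes; unreachable pairs are excluded and
#' their count is reported in the `"n_unreachable_pairs"` attribute.
#'
#' @rdname network-features
#' @export
net_shortest_path <- function(net) {
  A <- as_adjacency(net)
  n <- nrow(A)
  if (n < 2) {
    return(structure(NA_real_, n_unreachable_pairs = 0L))
  }
  D <- bfs_distances(A)
  up <- D[upper.tri(D)]
  reach <- is.finite(up)
  val <- if (any(reach)) mean(up[reach]) else NA_real_
  structure(val, n_unreachable_pairs = sum(!reach))
}

#' Mean betweenness centrality
#'
#' Per node `i`, the sum over ordered pairs `s != t` (both distinct from
#' `i`) of the fraction of shortest s-t paths passing through `i`
#' (Brandes' accumulation, unnormalised); the feature is the mean over all
#' nodes.  Unreachable pairs contribute nothing.
#'
#' @rdname network-features
#' @export
net_betweenness <- function(net) {
  A <- as_adjacency(net)
  n <- nrow(A)
  if (n == 0) return(NA_real_)
  mean(brandes_betweenness(A))
}

# Brandes (2001) betweenness for an unweighted undirected graph, ordered-pair
# convention: each unordered pair contributes from both endpoints
brandes_betweenness <- function(A) {
  n <- nrow(A)
  nbrs <- lapply(seq_len(n), function(i) which(A[i, ] == 1))
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n)
    sigma[s] <- 1
    dist <- rep(-1L, n)
    dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0)
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      order_visited <- c(order_visited, v)
      for (w in nbrs[[v]]) {
        if (dist[w] < 0) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc
}

#' Mean closeness centrality
#'
#' Per node, the inverse of the sum of shortest-path lengths to the other
#' nodes it can reach; nodes reaching nothing are excluded, and the feature
#' is the mean over the remaining nodes (undefined when every node is
#' isolated).
#'
#' @rdname network-features
#' @export
net_closeness <- function(net) {
  A <- as_adjacency(net)
  n <- nrow(A)
  if (n < 2) return(NA_real_)
  D <- bfs_distances(A)
  diag(D) <- NA
  cl <- apply(D, 1, function(row) {
    s <- sum(row[is.finite(row)], na.rm = TRUE)
    reach <- sum(is.finite(row) & !is.na(row))
    if (reach == 0) NA_real_ else 1 / s
  })
  if (all(is.na(cl))) return(NA_real_)
  mean(cl, na.rm = TRUE)
}

#' Feature vector of a behaviour network
#'
#' Assembles the eight features into a one-row data.frame.  For dynamic
#' networks `n_stops` is taken from the network (the stop count that fed
#' the clustering); for static networks the stop count is not defined and
#' reported as `NA` unless supplied.
#'
#' @rdname network-features
#' @param n_stops number of stops `o` to report (overrides the network's
#'   own `n_stops` field).
#' @return `net_features`: data.frame with columns `n_stops`, `order`,
#'   `degree`, `density`, `clustering`, `shortest_path`, `betweenness`,
#'   `closeness`, `n_unreachable_pairs`.
#' @export
net_features <- function(net, n_stops = NULL) {
  A <- as_adjacency(net)
  n <- nrow(A)
  if (is.null(n_stops)) {
    n_stops <- if (inherits(net, "behavior_network") &&
                   !is.null(net$n_stops)) net$n_stops else NA_integer_
  }
  l <- net_shortest_path(A)
  data.frame(
    n_stops = as.integer(n_stops),
    order = n,
    degree = net_degree(A),
    density = net_density(A),
    clustering = net_clustering(A),
    shortest_path = as.numeric(l),
    betweenness = net_betweenness(A),
    closeness = net_closeness(A),
    n_unreachable_pairs = attr(l, "n_unreachable_pairs")
  )
}
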