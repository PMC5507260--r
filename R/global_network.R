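#' Aggregate local networks into a group-day global network
#'
#' Pools the node centroids of all local networks of a group-day and
#' clusters them with the City Clustering Algorithm at the same
#' `cca_threshold` used to form the local networks; every local node is
#' thereby assigned to exactly one global node.  A global link joins two
#' distinct global nodes whenever some local link joins local nodes mapped
#' to them, weighted by the number of such supporting local links.  Each
#' global node carries a magnitude, the natural log of its member count
#' (used for rendering; singleton nodes with `ln 1 = 0` are drawn at a
#' minimum marker size).
#'
#' @param local_nets list of `behavior_network` objects (at least one with
#'   at least one node).
#' @param spec an [arena_spec()].
#' @param group,day labels stored on the result.
#' @return A `behavior_network` of kind `"global"` with extra fields
#'   `weights` (supporting-link count matrix), `member_map` (data.frame
#'   `net`, `local_id`, `global_id`), `magnitude` (per-node log member
#'   count), `n_local_nodes`, `group`, `day`.
#' @export
build_global <- function(local_nets, spec, group = "all", day = NA_integer_) {
  stopifnot(length(local_nets) >= 1, inherits(spec, "arena_spec"))
  coords <- list()
  index <- list()
  for (i in seq_along(local_nets)) {
    ln <- local_nets[[i]]
    stopifnot(inherits(ln, "behavior_network"))
    if (nrow(ln$nodes) == 0) next
    coords[[length(coords) + 1L]] <- cbind(ln$nodes$x, ln$nodes$y)
    index[[length(index) + 1L]] <- data.frame(
      net = i, local_id = seq_len(nrow(ln$nodes))
    )
  }
  if (length(coords) == 0) stop("no local nodes to aggregate")
  pts <- do.call(rbind, coords)
  member_map <- do.call(rbind, index)
  cl <- cca_cluster(pts, spec$cca_threshold)
  member_map$global_id <- cl$assignment
  k <- nrow(cl$centroids)
  A <- matrix(0, k, k)
  W <- matrix(0, k, k)
  for (i in unique(member_map$net)) {
    ln <- local_nets[[i]]
    map_i <- member_map$global_id[member_map$net == i]
    links <- which(ln$adjacency == 1 &
                     upper.tri(ln$adjacency), arr.ind = TRUE)
    if (nrow(links) == 0) next
    for (r in seq_len(nrow(links))) {
      gu <- map_i[links[r, 1]]
      gv <- map_i[links[r, 2]]
      if (gu != gv) {
        A[gu, gv] <- A[gv, gu] <- 1
        W[gu, gv] <- W[gv, gu] <- W[gu, gv] + 1
      }
    }
  }
  members <- as.integer(tabulate(cl$assignment, k))
  nodes <- data.frame(id = seq_len(k), x = cl$centroids[, 1],
                      y = cl$centroids[, 2], n_members = members)
  behavior_network(nodes, A, W, "global",
                   weights = W, member_map = member_map,
                   magnitude = log(members),
                   n_local_nodes = nrow(member_map),
                   group = group, day = day)
}

#' Degree-sorted polar topology layout
#'
#' Lays the global nodes out on polar coordinates by rank order of degree:
#' the highest-degree node at 0 degrees, the lowest at 360 degrees, with
#' the remaining nodes linearly spaced in between (ties broken by node id).
#' Each node gets one of five colour bins by degree `M`: white
#' (`M >= 12`), yellow (`12 > M >= 9`), orange (`9 > M >= 6`), red
#' (`6 > M >= 3`), brown (`3 > M`).
#'
#' @param gnet a `behavior_network` (normally of kind `"global"`).
#' @return data.frame with one row per node, sorted by rank: `id`,
#'   `degree`, `angle_deg`, `color`.
#' @export
polar_topology_layout <- function(gnet) {
  stopifnot(inherits(gnet, "behavior_network"), nrow(gnet$nodes) >= 1)
  deg <- rowSums(gnet$adjacency)
  ord <- order(-deg, gnet$nodes$id)
  n <- length(ord)
  angles <- if (n == 1) 0 else seq(0, 360, length.out = n)
  color <- as.character(cut(deg[ord], breaks = c(-Inf, 3, 6, 9, 12, Inf),
                            labels = c("brown", "red", "orange", "yellow",
                                       "white"),
                            right = FALSE))
  data.frame(id = gnet$nodes$id[ord], degree = deg[ord],
             angle_deg = angles, color = color)
}
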