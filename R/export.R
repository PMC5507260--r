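#' Convert a behaviour network to an igraph graph
#'
#' Nodes carry `x`, `y` and `n_members` attributes; edges carry `count`
#' (transition multiplicity) and, for global networks, `weight`
#' (supporting local links).
#'
#' @param net a `behavior_network`.
#' @return an [igraph::graph] object.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "behavior_network"))
  g <- igraph::graph_from_adjacency_matrix(net$adjacency,
                                           mode = "undirected")
  igraph::V(g)$name <- as.character(net$nodes$id)
  igraph::V(g)$x <- net$nodes$x
  igraph::V(g)$y <- net$nodes$y
  igraph::V(g)$n_members <- net$nodes$n_members
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g, names = FALSE)
    igraph::E(g)$count <- net$counts[el]
    if (!is.null(net$weights)) igraph::E(g)$weight <- net$weights[el]
  }
  g
}

#' Export a behaviour network as GraphML
#'
#' @param net a `behavior_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Export a behaviour network as node/edge CSVs
#'
#' Writes a node table (`id`, `x`, `y`, `n_members`) and an edge table
#' (`u`, `v`, `count`).
#'
#' @param net a `behavior_network`.
#' @param node_path,edge_path output file paths.
#' @return invisible character vector of the two paths.
#' @export
write_network_csv <- function(net, node_path, edge_path) {
  stopifnot(inherits(net, "behavior_network"))
  utils::write.csv(net$nodes, node_path, row.names = FALSE, quote = FALSE)
  idx <- which(net$adjacency == 1 & upper.tri(net$adjacency),
               arr.ind = TRUE)
  edges <- data.frame(u = net$nodes$id[idx[, 1]],
                      v = net$nodes$id[idx[, 2]],
                      count = net$counts[idx])
  utils::write.csv(edges, edge_path, row.names = FALSE, quote = FALSE)
  invisible(c(node_path, edge_path))
}

#' Plot a behaviour network over the arena
#'
#' Draws the arena edge and holes, the network links (line width scaled by
#' transition count) and the nodes (symbol size scaled by member count).
#'
#' @param x a `behavior_network`.
#' @param spec optional [arena_spec()] for the arena outline.
#' @param ... passed to [graphics::plot()].
#' @export
plot.behavior_network <- function(x, spec = NULL, ...) {
  rng <- if (!is.null(spec)) {
    c(spec$center[1] - spec$arena_radius, spec$center[1] + spec$arena_radius)
  } else {
    range(x$nodes$x, x$nodes$y)
  }
  graphics::plot(NA, xlim = rng, ylim = rev(rng), asp = 1,
                 xlab = "x (px)", ylab = "y (px)", ...)
  if (!is.null(spec)) {
    th <- seq(0, 2 * pi, length.out = 200)
    graphics::lines(spec$center[1] + spec$arena_radius * cos(th),
                    spec$center[2] + spec$arena_radius * sin(th),
                    col = "grey60")
    hp <- hole_positions(spec)
    graphics::points(hp, pch = 3, col = "grey40")
  }
  idx <- which(x$adjacency == 1 & upper.tri(x$adjacency), arr.ind = TRUE)
  if (nrow(idx) > 0) {
    graphics::segments(x$nodes$x[idx[, 1]], x$nodes$y[idx[, 1]],
                       x$nodes$x[idx[, 2]], x$nodes$y[idx[, 2]],
                       lwd = 0.5 + log1p(x$counts[idx]), col = "grey50")
  }
  graphics::points(x$nodes$x, x$nodes$y, pch = 21, bg = "tomato",
                   cex = 0.8 + 0.4 * log1p(x$nodes$n_members))
  invisible(x)
}

#' Plot the degree-sorted polar topology of a global network
#'
#' Nodes are placed on the unit circle at the angles of
#' [polar_topology_layout()] and links are drawn as chords; node fill
#' follows the five degree colour bins.
#'
#' @param gnet a `behavior_network` of kind `"global"`.
#' @param ... passed to [graphics::plot()].
#' @return the layout data.frame, invisibly.
#' @export
plot_polar_topology <- function(gnet, ...) {
  lay <- polar_topology_layout(gnet)
  a <- lay$angle_deg * pi / 180
  px <- cos(a)
  py <- sin(a)
  pos <- match(gnet$nodes$id, lay$id)
  graphics::plot(NA, xlim = c(-1.2, 1.2), ylim = c(-1.2, 1.2), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", ...)
  idx <- which(gnet$adjacency == 1 & upper.tri(gnet$adjacency),
               arr.ind = TRUE)
  if (nrow(idx) > 0) {
    graphics::segments(px[pos[idx[, 1]]], py[pos[idx[, 1]]],
                       px[pos[idx[, 2]]], py[pos[idx[, 2]]], col = "grey60")
  }
  fill <- c(white = "white", yellow = "gold", orange = "darkorange",
            red = "red3", brown = "tan4")[lay$color]
  graphics::points(px, py, pch = 21, bg = fill, cex = 1.6)
  invisible(lay)
}
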