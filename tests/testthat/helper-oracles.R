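# Brute-force oracles, independent of the package implementations.

# all-pairs shortest-path lengths by Floyd-Warshall
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

oracle_links <- function(A) {
  nrow(which(A == 1 & upper.tri(A), arr.ind = TRUE))
}

oracle_density <- function(A) {
  n <- nrow(A)
  oracle_links(A) / choose(n, 2)
}

# local clustering by triangle counting: C_i = 2 T_i / (k_i (k_i - 1))
oracle_clustering <- function(A) {
  deg <- rowSums(A)
  idx <- which(deg >= 2)
  if (length(idx) == 0) return(NA_real_)
  ci <- vapply(idx, function(i) {
    nb <- which(A[i, ] == 1)
    tri <- sum(A[nb, nb]) / 2
    2 * tri / (deg[i] * (deg[i] - 1))
  }, numeric(1))
  mean(ci)
}

oracle_mean_shortest_path <- function(A) {
  D <- oracle_distances(A)
  up <- D[upper.tri(D)]
  if (!any(is.finite(up))) return(NA_real_)
  mean(up[is.finite(up)])
}

# enumerate every geodesic between s and t as a list of node vectors
enumerate_geodesics <- function(A, D, s, t) {
  if (!is.finite(D[s, t])) return(list())
  if (s == t) return(list(s))
  out <- list()
  for (u in which(A[s, ] == 1)) {
    if (D[u, t] == D[s, t] - 1) {
      for (p in enumerate_geodesics(A, D, u, t)) {
        out[[length(out) + 1L]] <- c(s, p)
      }
    }
  }
  out
}

# per-node betweenness by exhaustive geodesic enumeration (ordered pairs)
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  x <- numeric(n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t || !is.finite(D[s, t])) next
      paths <- enumerate_geodesics(A, D, s, t)
      g_st <- length(paths)
      for (i in seq_len(n)) {
        if (i == s || i == t) next
        through <- sum(vapply(paths, function(p) i %in% p, logical(1)))
        x[i] <- x[i] + through / g_st
      }
    }
  }
  x
}

oracle_closeness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  diag(D) <- NA
  cl <- vapply(seq_len(n), function(i) {
    d <- D[i, ]
    d <- d[!is.na(d) & is.finite(d)]
    if (length(d) == 0) NA_real_ else 1 / sum(d)
  }, numeric(1))
  if (all(is.na(cl))) return(NA_real_)
  mean(cl, na.rm = TRUE)
}

# Erdos-Renyi adjacency matrix
random_graph <- function(n, p) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.numeric(stats::runif(length(up)) < p)
  A + t(A)
}

random_connected_graph <- function(n, p) {
  repeat {
    A <- random_graph(n, p)
    if (all(is.finite(oracle_distances(A)))) return(A)
  }
}

graph_path <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  A
}

graph_ring <- function(n) {
  A <- graph_path(n)
  A[1, n] <- A[n, 1] <- 1
  A
}

graph_star <- function(n) {
  A <- matrix(0, n, n)
  A[1, 2:n] <- A[2:n, 1] <- 1
  A
}

graph_complete <- function(n) {
  A <- matrix(1, n, n) - diag(n)
  A
}

# frame-by-frame stop-episode oracle: mark frames covered by any qualifying
# window, then take maximal runs
oracle_stop_episodes <- function(x, y, w, thr) {
  nf <- length(x)
  if (nf < w) {
    return(data.frame(start_frame = integer(0), end_frame = integer(0)))
  }
  stopped <- logical(nf)
  for (i in seq_len(nf - w + 1)) {
    pl <- 0
    for (j in i:(i + w - 2)) {
      pl <- pl + sqrt((x[j + 1] - x[j])^2 + (y[j + 1] - y[j])^2)
    }
    if (pl < thr) stopped[i:(i + w - 1)] <- TRUE
  }
  runs <- rle(stopped)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  data.frame(start_frame = starts[keep], end_frame = ends[keep])
}

# per-frame visit-event oracle: track which disk (if any) the frame is in
oracle_visit_events <- function(x, y, spec) {
  holes <- hole_positions(spec)
  events <- data.frame(hole = integer(0), enter_frame = integer(0),
                       exit_frame = integer(0))
  prev <- NA_integer_
  for (f in seq_along(x)) {
    d <- sqrt((holes[, 1] - x[f])^2 + (holes[, 2] - y[f])^2)
    inside <- which(d <= spec$hole_proximity_radius)
    cur <- if (length(inside) == 0) NA_integer_ else inside[which.min(d[inside])] - 1L
    if (!is.na(cur) && (is.na(prev) || cur != prev)) {
      events <- rbind(events, data.frame(hole = cur, enter_frame = f,
                                         exit_frame = f))
    } else if (!is.na(cur) && !is.na(prev) && cur == prev) {
      events$exit_frame[nrow(events)] <- f
    }
    prev <- cur
  }
  events
}

# quadrant-cross oracle over excursions through the centre zone
oracle_quadrant_crosses <- function(x, y, spec) {
  d <- sqrt((x - spec$center[1])^2 + (y - spec$center[2])^2)
  ang <- atan2(spec$center[2] - y, x - spec$center[1]) %% (2 * pi)
  q <- floor(ang / (pi / 2)) %% 4
  inzone <- d <= spec$center_zone_radius
  crosses <- 0
  i <- 1
  nf <- length(x)
  while (i <= nf) {
    if (inzone[i]) {
      entry_q <- if (i == 1) NA else q[i - 1]
      j <- i
      while (j <= nf && inzone[j]) j <- j + 1
      if (j <= nf && !is.na(entry_q) && q[j] != entry_q) {
        crosses <- crosses + 1
      }
      i <- j
    } else {
      i <- i + 1
    }
  }
  crosses
}
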