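# Shared fixture builders.

default_spec <- function(...) arena_spec(...)

# trajectory from raw coordinates at the nominal 5 Hz
make_traj <- function(x, y, spec = NULL, ...) {
  trajectory(t = (seq_along(x) - 1) / 5, x = x, y = y, ...)
}

# dense polyline through waypoints (rows of `wp`), step <= `step` px
polyline_traj <- function(wp, step = 5, ...) {
  xs <- wp[1, 1]
  ys <- wp[1, 2]
  for (i in seq_len(nrow(wp) - 1)) {
    seg <- wp[i + 1, ] - wp[i, ]
    len <- sqrt(sum(seg^2))
    k <- max(1, ceiling(len / step))
    tt <- seq_len(k) / k
    xs <- c(xs, wp[i, 1] + tt * seg[1])
    ys <- c(ys, wp[i, 2] + tt * seg[2])
  }
  make_traj(xs, ys, ...)
}

# bounded random walk inside the arena
random_walk_traj <- function(n, spec, step_sd = 10, ...) {
  x <- numeric(n)
  y <- numeric(n)
  x[1] <- spec$center[1]
  y[1] <- spec$center[2]
  for (i in 2:n) {
    repeat {
      cx <- x[i - 1] + stats::rnorm(1, 0, step_sd)
      cy <- y[i - 1] + stats::rnorm(1, 0, step_sd)
      d <- sqrt((cx - spec$center[1])^2 + (cy - spec$center[2])^2)
      if (d <= spec$arena_radius) break
    }
    x[i] <- cx
    y[i] <- cy
  }
  make_traj(x, y, ...)
}

# point on the arena at polar coordinates (degrees, radius)
pt <- function(angle_deg, r, spec) {
  a <- angle_deg * pi / 180
  c(spec$center[1] + r * cos(a), spec$center[2] - r * sin(a))
}
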