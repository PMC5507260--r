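#' Hole visit events
#'
#' A visit to a hole opens at the first frame inside that hole's proximity
#' disk (closed disk of radius `hole_proximity_radius`) after being outside
#' all hole disks, and closes when the disk is left; consecutive frames
#' inside count as a single visit.  With the default geometry the disks are
#' disjoint; should disks overlap, a frame is attributed to the nearest
#' hole.
#'
#' @param traj a [trajectory()] in the frame described by `spec`.
#' @param spec an [arena_spec()].
#' @return data.frame with one row per visit, ordered by entry:
#'   `hole` (0-based index), `enter_frame`, `exit_frame` (1-based, inclusive).
#' @export
hole_visit_events <- function(traj, spec) {
  stopifnot(inherits(traj, "maz_trajectory"), inherits(spec, "arena_spec"))
  xy <- traj_xy(traj)
  nf <- nrow(xy)
  empty <- data.frame(hole = integer(0), enter_frame = integer(0),
                      exit_frame = integer(0))
  if (nf == 0) return(empty)
  holes <- hole_positions(spec)
  d2 <- outer(xy[, 1], holes[, 1], "-")^2 + outer(xy[, 2], holes[, 2], "-")^2
  inside <- d2 <= spec$hole_proximity_radius^2
  cur <- ifelse(rowSums(inside) > 0, max.col(-d2, ties.method = "first") - 1L,
                NA_integer_)
  cur[rowSums(inside) == 0] <- NA_integer_
  r <- rle(ifelse(is.na(cur), -1L, cur))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values >= 0
  data.frame(hole = as.integer(r$values[keep]),
             enter_frame = as.integer(starts[keep]),
             exit_frame = as.integer(ends[keep]))
}

#' Number of errors
#'
#' Total number of visits to dummy (non-target) hole proximity disks over
#' the whole trial; repeat visits to the same dummy count each time.
#'
#' @inheritParams hole_visit_events
#' @return integer count.
#' @export
count_errors <- function(traj, spec) {
  ev <- hole_visit_events(traj, spec)
  sum(ev$hole != spec$target_index)
}

#' Latency to reach the target hole
#'
#' Time from the trial start to the first entry into the target proximity
#' disk.  Entry into the escape box itself is not observable from tracked
#' points, so first disk entry is used as its geometric proxy.  If the
#' target is never entered, the trial duration is returned and the
#' `"reached"` attribute is `FALSE`.
#'
#' @inheritParams hole_visit_events
#' @return numeric seconds with logical attribute `"reached"`.
#' @export
latency_to_target <- function(traj, spec) {
  ev <- hole_visit_events(traj, spec)
  t <- traj$frames$t
  hit <- ev$enter_frame[ev$hole == spec$target_index]
  if (length(hit) > 0) {
    structure(t[hit[1]] - t[1], reached = TRUE)
  } else {
    structure(t[length(t)] - t[1], reached = FALSE)
  }
}

#' Travel distance
#'
#' Sum of the norms of the displacement vectors between successive frames.
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @return numeric pixels.
#' @export
travel_distance <- function(traj) {
  stopifnot(inherits(traj, "maz_trajectory"))
  if (n_frames(traj) < 2) stop("travel_distance needs >= 2 frames")
  sum(sqrt(diff(traj$frames$x)^2 + diff(traj$frames$y)^2))
}

#' Time spent around each hole
#'
#' Per-hole count of frames spent within the hole's proximity disk (closed:
#' a frame exactly at the proximity radius counts).  A frame inside two
#' overlapping disks would count for both.
#'
#' @inheritParams hole_visit_events
#' @return integer vector of length `n_holes`, named by hole index.
#' @export
time_near_holes <- function(traj, spec) {
  xy <- traj_xy(traj)
  holes <- hole_positions(spec)
  d2 <- outer(xy[, 1], holes[, 1], "-")^2 + outer(xy[, 2], holes[, 2], "-")^2
  counts <- colSums(d2 <= spec$hole_proximity_radius^2)
  names(counts) <- seq_len(spec$n_holes) - 1L
  as.integer(counts)
}

#' Occupancy map
#'
#' Square-block occupancy rates over the arena bounding box: per block, the
#' fraction of trial frames falling in it.  Frames outside the arena disk
#' are excluded from the numerator (rates then sum to at most 1; exactly 1
#' for an in-arena trajectory).  Blocks are anchored at the bounding-box
#' corner, so halving `block_px` refines each block into exact quarters.
#'
#' @inheritParams hole_visit_events
#' @param block_px block edge length, pixels (default 20 px = 4 cm).
#' @return An object of class `occupancy_map`: list with `grid` (matrix of
#'   rates, rows = x blocks, cols = y blocks), `block_px`, `total_frames`,
#'   `x_breaks`, `y_breaks`.
#' @export
occupancy_map <- function(traj, spec, block_px = 20) {
  stopifnot(block_px > 0)
  xy <- traj_xy(traj)
  nf <- nrow(xy)
  x0 <- spec$center[1] - spec$arena_radius
  y0 <- spec$center[2] - spec$arena_radius
  nb <- ceiling(2 * spec$arena_radius / block_px)
  inside <- arena_dist(xy, spec) <= spec$arena_radius
  ix <- pmin(nb, pmax(1, floor((xy[inside, 1] - x0) / block_px) + 1L))
  iy <- pmin(nb, pmax(1, floor((xy[inside, 2] - y0) / block_px) + 1L))
  grid <- matrix(0, nb, nb)
  if (length(ix) > 0) {
    tab <- table(factor(ix, levels = seq_len(nb)),
                 factor(iy, levels = seq_len(nb)))
    grid <- unclass(tab) / nf
  }
  structure(list(
    grid = grid, block_px = block_px, total_frames = nf,
    x_breaks = x0 + block_px * (0:nb), y_breaks = y0 + block_px * (0:nb)
  ), class = "occupancy_map")
}

#' @export
print.occupancy_map <- function(x, ...) {
  cat(sprintf("<occupancy_map> %d x %d blocks of %g px, %d frames, mass %.3f\n",
              nrow(x$grid), ncol(x$grid), x$block_px, x$total_frames,
              sum(x$grid)))
  invisible(x)
}

#' @export
plot.occupancy_map <- function(x, ...) {
  graphics::image(x$x_breaks, x$y_breaks, x$grid,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "x (px)", ylab = "y (px)", useRaster = TRUE,
                  ylim = rev(range(x$y_breaks)), asp = 1, ...)
  invisible(x)
}

#' Per-subject per-day feature averages
#'
#' Arithmetic mean of each numeric feature across the trials of every
#' subject-day block (the within-day averaging applied before group-level
#' statistics), with the contributing trial count.
#'
#' @param features data.frame with one row per trial.
#' @param value_cols character vector of numeric feature columns to
#'   average; defaults to every numeric column outside `by`.
#' @param by grouping columns (default `subject_id`, `day`).
#' @return data.frame of group means plus `n_trials`.
#' @export
daily_average <- function(features, value_cols = NULL,
                          by = c("subject_id", "day")) {
  stopifnot(all(by %in% names(features)), nrow(features) > 0)
  if (is.null(value_cols)) {
    value_cols <- setdiff(names(features)[vapply(features, is.numeric,
                                                 logical(1))], by)
  }
  agg <- stats::aggregate(features[value_cols], features[by],
                          FUN = mean, na.rm = TRUE)
  n <- stats::aggregate(list(n_trials = features[[value_cols[1]]]),
                        features[by], FUN = length)
  merge(agg, n, by = by, sort = TRUE)
}

#' Conventional feature row for one trial
#'
#' Computes the classical per-trial measures in one call: error count,
#' latency (with reached flag), travel distance and per-hole dwell frames.
#'
#' @inheritParams hole_visit_events
#' @return one-row data.frame: `n_errors`, `latency_s`, `reached`,
#'   `travel_distance_px`, and `near_hole_<i>` frame counts.
#' @export
conventional_features <- function(traj, spec) {
  lat <- latency_to_target(traj, spec)
  near <- time_near_holes(traj, spec)
  out <- data.frame(
    n_errors = count_errors(traj, spec),
    latency_s = as.numeric(lat),
    reached = attr(lat, "reached"),
    travel_distance_px = travel_distance(traj)
  )
  near_df <- as.data.frame(as.list(near))
  names(near_df) <- paste0("near_hole_", seq_along(near) - 1L)
  cbind(out, near_df)
}
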