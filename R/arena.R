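#' Arena specification for a Barnes circular maze
#'
#' Defines the geometry and analysis thresholds shared by every stage of the
#' pipeline: the circular table, the ring of escape holes, the target hole,
#' the camera scale, and the stop-detection / clustering parameters.
#'
#' Coordinates follow the image convention of the acquisition system: origin
#' at the top-left of the frame, x increasing rightwards, y increasing
#' downwards.  Angles are measured counterclockwise as seen on screen (i.e.
#' "up" is 90 degrees), so the canonical top-right target sits at 45 degrees.
#' Defaults correspond to a 98-cm arena imaged at 2 mm/pixel into a
#' 500 x 500 frame at 5 Hz: arena radius 245 px, hole ring radius 200 px
#' (40 cm), 12 holes, 40-px hole proximity disks (about one mouse body
#' length), a 20-px / 5-frame stop criterion (about half a body length) and a
#' 20-px clustering threshold.
#'
#' @param center numeric length-2, arena centre in pixels.
#' @param arena_radius arena radius in pixels.
#' @param n_holes number of equally spaced perimeter holes.
#' @param hole_ring_radius radius of the circle of hole centroids, pixels.
#' @param hole_proximity_radius radius of the per-hole proximity disk used
#'   for visit and dwell counting, pixels.
#' @param target_index index of the target hole, `0 .. n_holes - 1`.
#' @param px_per_cm camera scale, pixels per centimetre.
#' @param frame_rate nominal acquisition rate, Hz.
#' @param center_zone_radius radius of the central zone used for
#'   quadrant-cross counting, pixels; defaults to a quarter of the arena
#'   radius.
#' @param stop_threshold path-length threshold (pixels) below which a
#'   sliding window of frames counts as stopped.
#' @param stop_window length of the stop-detection sliding window, frames.
#' @param cca_threshold distance threshold (pixels) of the City Clustering
#'   Algorithm used for dynamic-node and global-node formation.
#' @return An object of class `arena_spec` (a validated list).
#' @examples
#' spec <- arena_spec()
#' hole_positions(spec)
#' @export
arena_spec <- function(center = c(250, 250),
                       arena_radius = 245,
                       n_holes = 12L,
                       hole_ring_radius = 200,
                       hole_proximity_radius = 40,
                       target_index = 0L,
                       px_per_cm = 5,
                       frame_rate = 5,
                       center_zone_radius = 0.25 * arena_radius,
                       stop_threshold = 20,
                       stop_window = 5L,
                       cca_threshold = 20) {
  spec <- list(
    center = as.numeric(center),
    arena_radius = as.numeric(arena_radius),
    n_holes = as.integer(n_holes),
    hole_ring_radius = as.numeric(hole_ring_radius),
    hole_proximity_radius = as.numeric(hole_proximity_radius),
    target_index = as.integer(target_index),
    px_per_cm = as.numeric(px_per_cm),
    frame_rate = as.numeric(frame_rate),
    center_zone_radius = as.numeric(center_zone_radius),
    stop_threshold = as.numeric(stop_threshold),
    stop_window = as.integer(stop_window),
    cca_threshold = as.numeric(cca_threshold)
  )
  class(spec) <- "arena_spec"
  validate_arena_spec(spec)
}

validate_arena_spec <- function(spec) {
  stopifnot(
    length(spec$center) == 2, all(is.finite(spec$center)),
    spec$arena_radius > 0,
    spec$n_holes >= 2,
    spec$hole_ring_radius > 0,
    spec$hole_ring_radius < spec$arena_radius,
    spec$hole_proximity_radius > 0,
    spec$px_per_cm > 0,
    spec$frame_rate > 0,
    spec$center_zone_radius > 0,
    spec$stop_threshold > 0,
    spec$stop_window >= 2,
    spec$cca_threshold > 0
  )
  if (spec$target_index < 0 || spec$target_index >= spec$n_holes) {
    stop("target_index must lie in 0 .. n_holes - 1")
  }
  spec
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf(
    "<arena_spec> centre (%.1f, %.1f) px, radius %.1f px (%.1f cm)\n",
    x$center[1], x$center[2], x$arena_radius, x$arena_radius / x$px_per_cm
  ))
  cat(sprintf(
    "  %d holes on ring r = %.1f px, proximity %.1f px, target index %d\n",
    x$n_holes, x$hole_ring_radius, x$hole_proximity_radius, x$target_index
  ))
  cat(sprintf(
    "  frame rate %g Hz; stop: < %g px over %d frames; CCA threshold %g px\n",
    x$frame_rate, x$stop_threshold, x$stop_window, x$cca_threshold
  ))
  invisible(x)
}

#' Read or write an arena specification as JSON
#'
#' The JSON file holds every `arena_spec` field by name, making the geometry
#' an explicit, shareable part of an analysis.
#'
#' @param path file path of the JSON configuration.
#' @return `read_arena_spec` returns an `arena_spec`; `write_arena_spec`
#'   invisibly returns `path`.
#' @export
read_arena_spec <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(arena_spec))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    stop("unknown arena config fields: ", paste(unknown, collapse = ", "))
  }
  do.call(arena_spec, cfg)
}

#' @param spec an `arena_spec`.
#' @rdname read_arena_spec
#' @export
write_arena_spec <- function(spec, path) {
  stopifnot(inherits(spec, "arena_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# angle (radians, CCW as displayed, in [0, 2*pi)) of points about the centre;
# y grows downward in image coordinates, hence cy - y
arena_angle <- function(xy, spec) {
  xy <- matrix(xy, ncol = 2)
  a <- atan2(spec$center[2] - xy[, 2], xy[, 1] - spec$center[1])
  a %% (2 * pi)
}

# point(s) at polar coordinates (angle, r) about the arena centre
arena_point <- function(angle, r, spec) {
  cbind(spec$center[1] + r * cos(angle), spec$center[2] - r * sin(angle))
}

arena_dist <- function(xy, spec) {
  xy <- matrix(xy, ncol = 2)
  sqrt((xy[, 1] - spec$center[1])^2 + (xy[, 2] - spec$center[2])^2)
}

hole_angles <- function(spec) {
  pi / 4 + (seq_len(spec$n_holes) - 1) * 2 * pi / spec$n_holes
}

#' Hole positions on the arena
#'
#' Returns the centroids of the perimeter holes.  Hole 0 sits at the
#' canonical top-right angle (45 degrees) and indices increase
#' counterclockwise, so hole `i` lies at `45 + i * 360 / n_holes` degrees on
#' the hole ring.
#'
#' @param spec an [arena_spec()].
#' @return numeric matrix `n_holes x 2` of (x, y) pixel coordinates; row `i`
#'   is hole index `i - 1`.
#' @export
hole_positions <- function(spec) {
  stopifnot(inherits(spec, "arena_spec"))
  arena_point(hole_angles(spec), spec$hole_ring_radius, spec)
}

#' Rotate a trajectory into the canonical target-at-45-degrees frame
#'
#' Applies the rigid rotation about the arena centre that maps the target
#' hole onto the canonical top-right position (45 degrees).  Because the
#' hole ring is rotationally symmetric, hole slots are preserved and the
#' target occupies hole index 0 afterwards; pair the returned trajectory
#' with [canonical_spec()] when computing hole-indexed features.
#'
#' @param traj a [trajectory()].
#' @param spec an [arena_spec()] whose `target_index` identifies the target.
#' @return The rotated trajectory, flagged as canonical.  Distances from the
#'   centre (and all pairwise distances) are preserved.
#' @export
canonical_transform <- function(traj, spec) {
  stopifnot(inherits(traj, "maz_trajectory"), inherits(spec, "arena_spec"))
  if (isTRUE(traj$canonical)) {
    return(traj)
  }
  rot <- -spec$target_index * 2 * pi / spec$n_holes
  out <- traj
  if (nrow(traj$frames) > 0) {
    u <- traj$frames$x - spec$center[1]
    v <- spec$center[2] - traj$frames$y
    out$frames$x <- spec$center[1] + u * cos(rot) - v * sin(rot)
    out$frames$y <- spec$center[2] - (u * sin(rot) + v * cos(rot))
  }
  out$canonical <- TRUE
  out
}

#' @rdname canonical_transform
#' @return `canonical_spec` returns `spec` with `target_index` set to 0, the
#'   slot the target occupies after `canonical_transform`.
#' @export
canonical_spec <- function(spec) {
  stopifnot(inherits(spec, "arena_spec"))
  spec$target_index <- 0L
  spec
}

#' Quadrant of a point in the canonical frame
#'
#' Quadrant boundaries lie on the cardinal axes (0, 90, 180, 270 degrees) so
#' that the canonical target at 45 degrees sits mid-quadrant in quadrant 0;
#' quadrants are numbered counterclockwise.  A point exactly on a boundary
#' ray belongs to the counterclockwise quadrant.
#'
#' @param xy numeric length-2 point or an `n x 2` matrix of points (pixels).
#' @param spec an [arena_spec()].
#' @return integer quadrant id(s) in `0..3`.  Points outside the arena are
#'   flagged with a warning and assigned by angle all the same.
#' @export
quadrant_of <- function(xy, spec) {
  stopifnot(inherits(spec, "arena_spec"))
  xy <- matrix(xy, ncol = 2)
  outside <- arena_dist(xy, spec) > spec$arena_radius
  if (any(outside)) {
    warning(sum(outside), " point(s) outside the arena; nearest quadrant returned")
  }
  as.integer(floor(arena_angle(xy, spec) / (pi / 2)) %% 4)
}
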