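#' Parameters for the synthetic trajectory generator
#'
#' The generator produces 5-Hz arena trajectories from a discrete-time
#' correlated random walk.  Goal-directed archetypes (`"spatial"`,
#' `"serial"`) steer towards waypoints with small heading noise; the
#' `"random"` archetype performs a free correlated walk with scheduled
#' traversals through the arena centre; `"mixture"` draws one of the three
#' archetypes per trial with probabilities `strategy_probs`; `"sites"`
#' shuttles between user-supplied dwell sites (used for clustering
#' parameter-recovery experiments).
#'
#' Stops are realised as zero-mean jitter (marginal sd
#' `stop_threshold / 8`) around a fixed anchor for a geometric number of
#' frames; the jitter is a smooth AR(1) process, mimicking posture sway and
#' tracking noise, which are strongly autocorrelated at 5 Hz.
#'
#' @param strategy one of `"spatial"`, `"serial"`, `"random"`, `"mixture"`,
#'   `"sites"`.
#' @param speed_mean,speed_sd per-frame speed draw, px/s (truncated at 0).
#' @param turn_sd heading noise of the free correlated walk, radians/step.
#' @param goal_turn_sd heading noise while steering at a waypoint,
#'   radians/step.
#' @param stop_rate spontaneous stop episodes per second of travel.
#' @param stop_duration mean stop length, frames (geometric).
#' @param hole_dwell dwell length at each visited hole or site, frames.
#' @param serial_start_hole first hole of a serial circuit (default: the
#'   hole one slot counterclockwise of the target, so the circuit runs the
#'   long way round).
#' @param serial_direction `"ccw"` (increasing hole index) or `"cw"`.
#' @param random_center_cross_rate number of centre traversals scheduled
#'   per random-strategy trial.
#' @param escape_prob probability that an incidental visit to the target
#'   hole ends a random-search training trial (naive mice often overlook
#'   the escape hole on early passes).
#' @param min_explore_s minimum exploration time (seconds) before an
#'   incidental target visit can end a random-search trial.
#' @param max_duration trial cap, seconds.
#' @param start_dwell frames of on-release dwell at the start position.
#' @param strategy_probs length-3 numeric (spatial, serial, random) used by
#'   `strategy = "mixture"`.
#' @param dwell_sites `K x 2` matrix of dwell-site coordinates for
#'   `strategy = "sites"`.
#' @param jitter_ar autocorrelation of the stop/dwell jitter process.
#' @param seed integer seed making the trial reproducible.
#' @return An object of class `sim_params` (a validated list).
#' @export
sim_params <- function(strategy = c("spatial", "serial", "random",
                                    "mixture", "sites"),
                       speed_mean = 50, speed_sd = 15,
                       turn_sd = 0.5, goal_turn_sd = 0.12,
                       stop_rate = 0.2, stop_duration = 8,
                       hole_dwell = 8L,
                       serial_start_hole = NULL,
                       serial_direction = c("ccw", "cw"),
                       random_center_cross_rate = 6,
                       escape_prob = 0.1,
                       min_explore_s = 60,
                       max_duration = 180,
                       start_dwell = 5L,
                       strategy_probs = c(spatial = 1, serial = 0, random = 0) / 1,
                       dwell_sites = NULL,
                       jitter_ar = 0.7,
                       seed = 1L) {
  strategy <- match.arg(strategy)
  serial_direction <- match.arg(serial_direction)
  stopifnot(
    speed_mean > 0, speed_sd >= 0, turn_sd >= 0, goal_turn_sd >= 0,
    stop_rate >= 0, stop_duration >= 0, hole_dwell >= 0,
    random_center_cross_rate >= 0, escape_prob >= 0, escape_prob <= 1,
    min_explore_s >= 0,
    max_duration > 0, start_dwell >= 0, jitter_ar >= 0, jitter_ar < 1
  )
  if (strategy == "mixture") {
    stopifnot(length(strategy_probs) == 3, all(strategy_probs >= 0),
              sum(strategy_probs) > 0)
  }
  if (strategy == "sites") {
    stopifnot(!is.null(dwell_sites), ncol(dwell_sites) == 2,
              nrow(dwell_sites) >= 1)
  }
  structure(list(
    strategy = strategy, speed_mean = speed_mean, speed_sd = speed_sd,
    turn_sd = turn_sd, goal_turn_sd = goal_turn_sd, stop_rate = stop_rate,
    stop_duration = stop_duration, hole_dwell = as.integer(hole_dwell),
    serial_start_hole = serial_start_hole,
    serial_direction = serial_direction,
    random_center_cross_rate = random_center_cross_rate,
    escape_prob = escape_prob, min_explore_s = min_explore_s,
    max_duration = max_duration,
    start_dwell = as.integer(start_dwell),
    strategy_probs = strategy_probs, dwell_sites = dwell_sites,
    jitter_ar = jitter_ar, seed = as.integer(seed)
  ), class = "sim_params")
}

# evaluate `code` under `seed` without disturbing the caller's RNG stream
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Simulate a single maze trial
#'
#' Generates one trajectory on the arena under the locomotion model of
#' [sim_params()].  Training-phase trials end when the animal settles at the
#' target hole (goal-directed archetypes) or escapes during an incidental
#' target visit (random archetype, probability `escape_prob` per visit);
#' probe-phase trials always run for `max_duration`.  All points are
#' confined to the arena by a reflecting boundary, and the result is
#' reproducible from `params$seed`.
#'
#' The frame intervals of injected stop and dwell episodes are attached as
#' the `"planted_stops"` attribute (columns `start_frame`, `end_frame`,
#' `x`, `y`, `kind`), giving ground truth for stop-detection
#' parameter-recovery experiments.
#'
#' @param params a [sim_params()].
#' @param spec an [arena_spec()].
#' @param subject_id,day,trial,entry,phase trial descriptors.
#' @return A `maz_trajectory` in the frame defined by `spec` (the target at
#'   its `target_index` slot).
#' @export
simulate_trial <- function(params, spec, subject_id = "sim", day = 1L,
                           trial = 1L, entry = "LIFT", phase = "training") {
  stopifnot(inherits(params, "sim_params"), inherits(spec, "arena_spec"))
  local_seed(params$seed, simulate_trial_impl(params, spec, subject_id,
                                              day, trial, entry, phase))
}

simulate_trial_impl <- function(params, spec, subject_id, day, trial,
                                entry, phase) {
  strategy <- params$strategy
  if (strategy == "mixture") {
    strategy <- sample(c("spatial", "serial", "random"), 1,
                       prob = params$strategy_probs)
  }
  dt <- 1 / spec$frame_rate
  max_frames <- max(2L, round(params$max_duration * spec$frame_rate))
  holes <- hole_positions(spec)
  target_pos <- holes[spec$target_index + 1L, ]
  jit_sd <- spec$stop_threshold / 8
  phi <- params$jitter_ar
  arrive_tol <- 15

  # waypoint plan: rows are (x, y); attribute "dwell" marks dwell waypoints
  waypoints <- NULL
  if (strategy == "spatial") {
    waypoints <- rbind(target_pos)
  } else if (strategy == "serial") {
    start_hole <- params$serial_start_hole
    if (is.null(start_hole)) {
      start_hole <- (spec$target_index + 1L) %% spec$n_holes
    }
    step <- if (params$serial_direction == "ccw") 1L else -1L
    seq_holes <- start_hole
    h <- start_hole
    while (h != spec$target_index) {
      h <- (h + step) %% spec$n_holes
      seq_holes <- c(seq_holes, h)
    }
    waypoints <- holes[seq_holes + 1L, , drop = FALSE]
  } else if (strategy == "sites") {
    waypoints <- params$dwell_sites
  }

  start <- if (strategy == "sites") {
    params$dwell_sites[1, ] + stats::rnorm(2, 0, 1)
  } else {
    spec$center + stats::rnorm(2, 0, 2)
  }
  start <- clamp_to_arena(start, spec)

  n_cross <- round(params$random_center_cross_rate)
  cross_frames <- if (strategy == "random" && n_cross > 0) {
    round(seq(0.08, 0.85, length.out = n_cross) * max_frames)
  } else {
    integer(0)
  }

  xs <- ys <- numeric(max_frames)
  pos <- start
  heading <- stats::runif(1, 0, 2 * pi)
  jit <- stats::rnorm(2, 0, jit_sd)
  mode <- if (params$start_dwell > 0 && strategy != "sites") "dwell" else "travel"
  dwell_left <- params$start_dwell
  dwell_kind <- "start"
  anchor <- pos
  wp_i <- 1L
  maneuver <- 0L # 0 none, 1 heading to centre, 2 heading to exit point
  exit_point <- NULL
  next_cross <- 1L
  inside_target <- FALSE
  planted <- list()
  ep_start <- if (mode == "dwell") 1L else NA_integer_
  done_at <- NA_integer_

  for (i in seq_len(max_frames)) {
    if (mode %in% c("dwell", "stop")) {
      jit <- phi * jit + stats::rnorm(2, 0, jit_sd * sqrt(1 - phi^2))
      pos <- clamp_to_arena(anchor + jit, spec)
      dwell_left <- dwell_left - 1L
      if (dwell_left <= 0L) {
        planted[[length(planted) + 1L]] <- data.frame(
          start_frame = ep_start, end_frame = i, x = anchor[1],
          y = anchor[2], kind = dwell_kind, stringsAsFactors = FALSE
        )
        if (dwell_kind == "terminal") {
          done_at <- i
        } else if (dwell_kind %in% c("hole", "site")) {
          wp_i <- wp_i + 1L
          if (!is.null(waypoints) && wp_i > nrow(waypoints)) done_at <- i
        }
        mode <- "travel"
      }
      xs[i] <- pos[1]
      ys[i] <- pos[2]
      if (!is.na(done_at)) break
      next
    }

    # travel frame ---------------------------------------------------------
    if (strategy == "random" && maneuver == 0L &&
        next_cross <= length(cross_frames) && i >= cross_frames[next_cross]) {
      maneuver <- 1L
      next_cross <- next_cross + 1L
    }
    goal <- NULL
    if (!is.null(waypoints) && wp_i <= nrow(waypoints)) {
      goal <- waypoints[wp_i, ]
    } else if (maneuver == 1L) {
      goal <- spec$center
    } else if (maneuver == 2L) {
      goal <- exit_point
    }
    if (is.null(goal)) {
      heading <- heading + stats::rnorm(1, 0, params$turn_sd)
    } else {
      # angle towards goal in image coordinates (y down)
      heading <- atan2(-(goal[2] - pos[2]), goal[1] - pos[1]) +
        stats::rnorm(1, 0, params$goal_turn_sd)
    }
    speed <- max(0, stats::rnorm(1, params$speed_mean, params$speed_sd))
    cand <- pos + speed * dt * c(cos(heading), -sin(heading))
    refl <- reflect_at_boundary(cand, heading, spec)
    pos <- refl$pos
    heading <- refl$heading
    xs[i] <- pos[1]
    ys[i] <- pos[2]

    # arrivals
    if (!is.null(waypoints) && wp_i <= nrow(waypoints) &&
        sqrt(sum((pos - waypoints[wp_i, ])^2)) < arrive_tol) {
      mode <- "dwell"
      dwell_left <- max(1L, params$hole_dwell)
      dwell_kind <- if (strategy == "sites") "site" else "hole"
      anchor <- pos
      jit <- stats::rnorm(2, 0, jit_sd)
      ep_start <- i + 1L
      next
    }
    if (maneuver == 1L &&
        arena_dist(pos, spec) < 0.5 * spec$center_zone_radius) {
      q_now <- quadrant_of(pos, spec)
      q_exit <- sample(setdiff(0:3, q_now), 1)
      ang <- (q_exit * 90 + stats::runif(1, 15, 75)) * pi / 180
      exit_point <- as.numeric(arena_point(ang, 0.75 * spec$arena_radius, spec))
      maneuver <- 2L
    } else if (maneuver == 2L &&
               sqrt(sum((pos - exit_point)^2)) < 1.5 * arrive_tol) {
      maneuver <- 0L
    }

    # incidental escape for undirected search (training phase only); naive
    # animals do not recognise the escape hole during early exploration
    if (strategy == "random" && phase == "training" &&
        i > params$min_explore_s * spec$frame_rate) {
      in_target <- sqrt(sum((pos - target_pos)^2)) <= spec$hole_proximity_radius
      if (in_target && !inside_target &&
          stats::runif(1) < params$escape_prob) {
        mode <- "dwell"
        dwell_left <- max(1L, params$hole_dwell)
        dwell_kind <- "terminal"
        anchor <- pos
        jit <- stats::rnorm(2, 0, jit_sd)
        ep_start <- i + 1L
        inside_target <- in_target
        next
      }
      inside_target <- in_target
    }

    # spontaneous stop
    if (maneuver == 0L && params$stop_rate > 0 &&
        stats::runif(1) < params$stop_rate * dt) {
      mode <- "stop"
      dwell_kind <- "stop"
      p_stop <- 1 / max(params$stop_duration, 1)
      dwell_left <- 1L + stats::rgeom(1, p_stop)
      anchor <- pos
      jit <- stats::rnorm(2, 0, jit_sd)
      ep_start <- i + 1L
    }
  }

  n_used <- if (is.na(done_at)) max_frames else done_at
  n_used <- max(n_used, 2L)
  tr <- trajectory(
    t = (seq_len(n_used) - 1) / spec$frame_rate,
    x = xs[seq_len(n_used)], y = ys[seq_len(n_used)],
    subject_id = subject_id, day = day, trial = trial,
    entry = entry, phase = phase
  )
  planted <- if (length(planted) > 0) {
    do.call(rbind, planted)
  } else {
    data.frame(start_frame = integer(0), end_frame = integer(0),
               x = numeric(0), y = numeric(0), kind = character(0))
  }
  planted <- planted[planted$end_frame <= n_used, , drop = FALSE]
  attr(tr, "planted_stops") <- planted
  attr(tr, "strategy") <- strategy
  tr
}

clamp_to_arena <- function(pos, spec) {
  d <- sqrt(sum((pos - spec$center)^2))
  lim <- spec$arena_radius - 1e-9
  if (d > lim) {
    pos <- spec$center + (pos - spec$center) * lim / d
  }
  pos
}

# radial reflection at the table edge: fold the overshoot back inside and
# bounce the heading off the tangent
reflect_at_boundary <- function(pos, heading, spec) {
  d <- sqrt(sum((pos - spec$center)^2))
  R <- spec$arena_radius
  if (d > R) {
    over <- min(d - R, R * 0.9)
    u <- (pos - spec$center) / d
    pos <- spec$center + u * (R - over)
    normal_ang <- atan2(-(u[2]), u[1])
    heading <- 2 * normal_ang + pi - heading
  }
  list(pos = pos, heading = heading)
}

#' Simulate a cohort over a training schedule
#'
#' Generates `n_subjects x length(schedule) x trials_per_day` trials.  Each
#' schedule entry is the [sim_params()] in force on that day (typically a
#' `"mixture"` whose weights shift from random towards spatial search as
#' learning progresses).  Per-trial seeds are derived deterministically from
#' `seed`, so the cohort is byte-identical on re-runs.
#'
#' @param n_subjects number of subjects.
#' @param schedule list of [sim_params()], one per day (day `d` uses
#'   `schedule[[d]]`).
#' @param spec an [arena_spec()].
#' @param seed master seed.
#' @param trials_per_day trials per subject per day.
#' @param entry release method recorded for all trials.
#' @return A [trial_set()].
#' @export
simulate_cohort <- function(n_subjects, schedule, spec, seed = 1L,
                            trials_per_day = 3L, entry = "LIFT") {
  stopifnot(length(schedule) >= 1, n_subjects >= 1)
  base <- as.integer(seed)
  trials <- list()
  for (s in seq_len(n_subjects)) {
    for (d in seq_along(schedule)) {
      for (k in seq_len(trials_per_day)) {
        p <- schedule[[d]]
        p$seed <- (abs(base) * 100003L + s * 1009L + d * 101L + k) %%
          2147483629L
        trials[[length(trials) + 1L]] <- simulate_trial(
          p, spec, subject_id = sprintf("m%02d", s), day = d, trial = k,
          entry = entry, phase = "training"
        )
      }
    }
  }
  trial_set(trials, spec)
}

#' A schedule of shifting strategy mixtures
#'
#' Convenience builder of a 6-day training schedule whose archetype mixture
#' moves from fully random search on day 1 towards predominantly spatial
#' search on day 6, emulating the course of spatial learning.
#'
#' @param days number of days.
#' @param ... overrides passed to every day's [sim_params()].
#' @return list of `sim_params` of length `days`.
#' @export
learning_schedule <- function(days = 6L, ...) {
  # rapid early improvement then plateau, as in published learning curves
  w_random <- 0.55^(seq_len(days) - 1)
  w_random[days] <- 0
  w_spatial <- c(0, 0.25, 0.45, 0.65, 0.8, 0.9)[pmin(seq_len(days), 6)]
  lapply(seq_len(days), function(d) {
    probs <- c(spatial = w_spatial[d],
               serial = max(0, 1 - w_spatial[d] - w_random[d]),
               random = w_random[d])
    sim_params(strategy = "mixture", strategy_probs = probs / sum(probs), ...)
  })
}
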