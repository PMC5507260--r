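#' Construct a trajectory for a single maze trial
#'
#' A trajectory is the ordered sequence of tracked positions of one animal
#' in one trial, together with the trial descriptors used by grouping and
#' preprocessing (subject, day, trial number, entry method, protocol phase).
#'
#' @param t numeric vector of frame times in seconds, strictly increasing.
#' @param x,y numeric vectors of positions in pixels (image convention:
#'   origin top-left, y downwards).
#' @param subject_id subject identifier.
#' @param day training day (integer, habituation = 0).
#' @param trial trial number within the day (integer >= 1).
#' @param entry release method, `"MANUAL"` (hand release from a cylinder) or
#'   `"LIFT"` (automated centre lift).
#' @param phase protocol phase: `"training"`, `"habituation"` or `"probe"`.
#' @param n_dropped number of input rows discarded during reading (kept for
#'   reporting).
#' @return An object of class `maz_trajectory`.
#' @examples
#' tr <- trajectory(t = c(0, 0.2, 0.4), x = c(250, 252, 254), y = rep(250, 3))
#' travel_distance(tr)
#' @export
trajectory <- function(t, x, y,
                       subject_id = "s1", day = 1L, trial = 1L,
                       entry = c("MANUAL", "LIFT"),
                       phase = c("training", "habituation", "probe"),
                       n_dropped = 0L) {
  entry <- match.arg(entry)
  phase <- match.arg(phase)
  stopifnot(length(t) == length(x), length(t) == length(y))
  if (length(t) < 2) stop("a trajectory needs at least 2 frames")
  if (any(!is.finite(t)) || any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values in trajectory frames")
  }
  if (any(diff(t) <= 0)) stop("frame times must be strictly increasing")
  new_trajectory(
    data.frame(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y)),
    subject_id = subject_id, day = day, trial = trial,
    entry = entry, phase = phase, n_dropped = n_dropped
  )
}

# unchecked constructor; also used for empty (invalid) trajectories
new_trajectory <- function(frames, subject_id, day, trial, entry, phase,
                           canonical = FALSE, n_dropped = 0L,
                           invalid = FALSE) {
  structure(
    list(
      frames = frames,
      subject_id = as.character(subject_id),
      day = as.integer(day),
      trial = as.integer(trial),
      entry = entry,
      phase = phase,
      canonical = canonical,
      n_dropped = as.integer(n_dropped),
      invalid = invalid
    ),
    class = "maz_trajectory"
  )
}

#' @export
print.maz_trajectory <- function(x, ...) {
  dur <- if (nrow(x$frames) > 1) diff(range(x$frames$t)) else 0
  cat(sprintf(
    "<trajectory> %s day %d trial %d (%s, %s): %d frames, %.1f s%s%s\n",
    x$subject_id, x$day, x$trial, x$entry, x$phase,
    nrow(x$frames), dur,
    if (x$canonical) ", canonical" else "",
    if (x$invalid) ", INVALID" else ""
  ))
  invisible(x)
}

#' @export
as.data.frame.maz_trajectory <- function(x, ...) {
  x$frames
}

n_frames <- function(traj) nrow(traj$frames)

traj_xy <- function(traj) cbind(traj$frames$x, traj$frames$y)

trial_key <- function(traj) {
  paste(traj$subject_id, traj$day, traj$trial, sep = "/")
}

#' Read a point-sequence file into a trajectory
#'
#' Reads a plain-text table of tracked positions, one row per frame.
#' The field separator (comma or tab) and the presence of a header are
#' sniffed from the first line.  The first three used columns are
#' frame-or-time, x and y; with a header, columns named `frame`, `t` (or
#' `time`), `x` and `y` are picked up by name and `columns` can remap them.
#' Rows with non-finite coordinates are dropped and counted in the
#' `n_dropped` field of the result.
#'
#' @param path path of the CSV/TSV file.
#' @param subject_id,day,trial,entry,phase trial descriptors (see
#'   [trajectory()]).
#' @param frame_rate frames per second, used to derive times from frame
#'   indices (`t = frame / frame_rate`).
#' @param time_col `"auto"` (default), `"frame"` or `"t"`: how to interpret
#'   the first column.  Under `"auto"`, an integer-valued column is treated
#'   as frame indices.
#' @param columns optional named character vector remapping header names,
#'   e.g. `c(frame = "idx", x = "px", y = "py")`.
#' @return A `maz_trajectory`.
#' @export
read_points <- function(path, subject_id = "s1", day = 1L, trial = 1L,
                        entry = c("MANUAL", "LIFT"),
                        phase = c("training", "habituation", "probe"),
                        frame_rate = 5, time_col = c("auto", "frame", "t"),
                        columns = NULL) {
  entry <- match.arg(entry)
  phase <- match.arg(phase)
  time_col <- match.arg(time_col)
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("empty file: ", path)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(fields))))
  dat <- utils::read.table(path, sep = sep, header = has_header,
                           stringsAsFactors = FALSE)
  if (has_header) {
    nm <- c(frame = "frame", t = "t", time = "time", x = "x", y = "y")
    if (!is.null(columns)) nm[names(columns)] <- columns
    xcol <- match(nm[["x"]], names(dat))
    ycol <- match(nm[["y"]], names(dat))
    tcol <- match(nm[["t"]], names(dat))
    if (is.na(tcol)) tcol <- match(nm[["time"]], names(dat))
    fcol <- match(nm[["frame"]], names(dat))
    if (is.na(xcol) || is.na(ycol)) stop("x/y columns not found in ", path)
    if (!is.na(tcol)) {
      raw_t <- dat[[tcol]]
      is_frames <- FALSE
    } else if (!is.na(fcol)) {
      raw_t <- dat[[fcol]]
      is_frames <- TRUE
    } else {
      stop("no frame or time column found in ", path)
    }
    raw_x <- dat[[xcol]]
    raw_y <- dat[[ycol]]
  } else {
    if (ncol(dat) < 3) stop("need at least 3 columns in ", path)
    raw_t <- dat[[1]]
    raw_x <- dat[[2]]
    raw_y <- dat[[3]]
    is_frames <- switch(time_col,
      frame = TRUE,
      t = FALSE,
      auto = all(is.finite(raw_t)) && all(raw_t == round(raw_t))
    )
  }
  raw_t <- as.numeric(raw_t)
  keep <- is.finite(raw_t) & is.finite(as.numeric(raw_x)) &
    is.finite(as.numeric(raw_y))
  n_dropped <- sum(!keep)
  t <- raw_t[keep]
  if (is_frames) t <- t / frame_rate
  if (sum(keep) < 2) stop("fewer than 2 valid rows in ", path)
  trajectory(t, as.numeric(raw_x)[keep], as.numeric(raw_y)[keep],
             subject_id = subject_id, day = day, trial = trial,
             entry = entry, phase = phase, n_dropped = n_dropped)
}

#' Write a trajectory as a `t,x,y` CSV
#'
#' @param traj a `maz_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_points <- function(traj, path) {
  stopifnot(inherits(traj, "maz_trajectory"))
  utils::write.csv(format(traj$frames, digits = 12, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Discard pre-release frames of a lift-entry trial
#'
#' Lift-released animals spend the first frames nearly motionless on the
#' lift scaffold; those micromovements would otherwise be scored as search
#' behaviour.  The trajectory is cut to the suffix starting at the first
#' frame whose distance from the arena centre exceeds `distance_threshold`.
#'
#' The default threshold of 38 px mirrors the spread of initial positions
#' observed under hand release (about half of a 15.25-cm diameter at
#' 5 px/cm); [manual_start_threshold()] recomputes it from a set of
#' MANUAL-entry trials.
#'
#' @param traj a `maz_trajectory` with `entry == "LIFT"`.  Applying the trim
#'   to a MANUAL trial is a no-op with a warning.
#' @param spec an [arena_spec()].
#' @param distance_threshold release radius in pixels.
#' @return The trimmed trajectory (a contiguous suffix of the input).  If
#'   the threshold is never exceeded an empty trajectory flagged `invalid`
#'   is returned.
#' @export
trim_lift_start <- function(traj, spec, distance_threshold = 38) {
  stopifnot(inherits(traj, "maz_trajectory"), inherits(spec, "arena_spec"))
  if (traj$entry != "LIFT") {
    warning("trim_lift_start applied to a ", traj$entry, " trial; no-op")
    return(traj)
  }
  d <- arena_dist(traj_xy(traj), spec)
  first <- which(d > distance_threshold)[1]
  out <- traj
  if (is.na(first)) {
    out$frames <- traj$frames[0, ]
    out$invalid <- TRUE
  } else {
    out$frames <- traj$frames[first:nrow(traj$frames), , drop = FALSE]
    rownames(out$frames) <- NULL
  }
  out
}

#' Release-radius threshold from MANUAL-entry trials
#'
#' Mean first-frame distance from the arena centre across a set of
#' MANUAL-entry trials; used as the `distance_threshold` of
#' [trim_lift_start()].
#'
#' @param trials a [trial_set()] or list of trajectories.
#' @param spec an [arena_spec()].
#' @return numeric scalar, pixels.
#' @export
manual_start_threshold <- function(trials, spec) {
  trajs <- if (inherits(trials, "maz_trial_set")) trials$trials else trials
  manual <- Filter(function(tr) tr$entry == "MANUAL", trajs)
  if (length(manual) == 0) stop("no MANUAL trials supplied")
  mean(vapply(manual, function(tr) {
    arena_dist(traj_xy(tr)[1, , drop = FALSE], spec)
  }, numeric(1)))
}

#' A set of trials sharing one arena
#'
#' @param trials list of [trajectory()] objects with unique
#'   (subject, day, trial) keys.
#' @param spec the shared [arena_spec()].
#' @return An object of class `maz_trial_set`.
#' @export
trial_set <- function(trials, spec) {
  stopifnot(inherits(spec, "arena_spec"), length(trials) >= 1)
  keys <- vapply(trials, trial_key, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate (subject, day, trial) keys in trial set")
  }
  structure(list(trials = trials, spec = spec), class = "maz_trial_set")
}

#' @export
print.maz_trial_set <- function(x, ...) {
  subj <- unique(vapply(x$trials, function(tr) tr$subject_id, character(1)))
  days <- unique(vapply(x$trials, function(tr) tr$day, integer(1)))
  cat(sprintf("<trial_set> %d trials, %d subjects, days %s\n",
              length(x$trials), length(subj),
              paste(sort(days), collapse = ",")))
  invisible(x)
}

#' @export
length.maz_trial_set <- function(x) length(x$trials)

#' Write / read a trial set as per-trial CSVs plus a manifest
#'
#' `write_trial_set` writes one `t,x,y` CSV per trial and a
#' `manifest.csv` listing file names and trial descriptors;
#' `read_trial_set` reads them back.
#'
#' @param ts a [trial_set()].
#' @param dir output directory (created if needed).
#' @return `write_trial_set` invisibly returns the manifest path;
#'   `read_trial_set` returns a `maz_trial_set`.
#' @export
write_trial_set <- function(ts, dir) {
  stopifnot(inherits(ts, "maz_trial_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(ts$trials), function(i) {
    tr <- ts$trials[[i]]
    file <- sprintf("%s_d%02d_t%02d.csv", tr$subject_id, tr$day, tr$trial)
    write_points(tr, file.path(dir, file))
    data.frame(file = file, subject_id = tr$subject_id, day = tr$day,
               trial = tr$trial, entry = tr$entry, phase = tr$phase,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  write_arena_spec(ts$spec, file.path(dir, "arena.json"))
  invisible(file.path(dir, "manifest.csv"))
}

#' @param manifest_path path of a manifest CSV written by `write_trial_set`
#'   (columns `file, subject_id, day, trial, entry, phase`).
#' @param spec arena specification; if `NULL`, `arena.json` next to the
#'   manifest is read.
#' @rdname write_trial_set
#' @export
read_trial_set <- function(manifest_path, spec = NULL) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  if (is.null(spec)) spec <- read_arena_spec(file.path(base, "arena.json"))
  trials <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    read_points(file.path(base, m$file), subject_id = m$subject_id,
                day = m$day, trial = m$trial, entry = m$entry,
                phase = m$phase, frame_rate = spec$frame_rate)
  })
  trial_set(trials, spec)
}
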