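#' Quadrant-cross count
#'
#' Counts centre-zone traversals that connect different quadrants: an
#' excursion counts when the animal enters the central zone (disk of
#' `center_zone_radius`) from one quadrant and exits into a different one.
#' Entering and returning to the same quadrant does not count, and a trial
#' that starts inside the centre zone has no entry quadrant for its first
#' exit.  This operationalises the "many centre crossings" that distinguish
#' unorganised search from perimeter runs.
#'
#' @param traj a [trajectory()] in the canonical frame (lift-entry trials
#'   should be trimmed with [trim_lift_start()] first).
#' @param spec an [arena_spec()].
#' @return integer count.
#' @export
quadrant_cross_count <- function(traj, spec) {
  stopifnot(inherits(traj, "maz_trajectory"), inherits(spec, "arena_spec"))
  xy <- traj_xy(traj)
  nf <- nrow(xy)
  if (nf < 2) return(0L)
  inzone <- arena_dist(xy, spec) <= spec$center_zone_radius
  q <- suppressWarnings(quadrant_of(xy, spec))
  crosses <- 0L
  entry_q <- NA_integer_
  for (i in 2:nf) {
    if (!inzone[i - 1] && inzone[i]) {
      entry_q <- q[i - 1]
    } else if (inzone[i - 1] && !inzone[i]) {
      if (!is.na(entry_q) && q[i] != entry_q) crosses <- crosses + 1L
      entry_q <- NA_integer_
    }
  }
  crosses
}

#' Is a hole-visit sequence sequential?
#'
#' TRUE when every consecutive pair of distinct visited holes is
#' ring-adjacent (indices differing by 1 modulo `n_holes`); direction
#' reversals are permitted, skips are not.  Sequences with fewer than two
#' distinct consecutive visits are vacuously sequential.
#'
#' @param visit_sequence integer vector of 0-based hole indices in visit
#'   order (consecutive duplicates are collapsed internally).
#' @param n_holes number of holes on the ring.
#' @param allow_skip if TRUE, a single skipped hole (index difference 2)
#'   also counts as adjacent.
#' @return logical flag.
#' @export
is_sequential <- function(visit_sequence, n_holes, allow_skip = FALSE) {
  v <- as.integer(visit_sequence)
  v <- v[c(TRUE, diff(v) != 0)]
  if (length(v) < 2) return(TRUE)
  d <- diff(v) %% n_holes
  ok <- c(1L, n_holes - 1L)
  if (allow_skip) ok <- c(ok, 2L, n_holes - 2L)
  all(d %in% ok)
}

#' Classify the search strategy of a training trial
#'
#' Applies the rule-based decision, evaluated in order:
#' \itemize{
#'   \item \strong{spatial}: 0 quadrant crosses and fewer than 3 errors;
#'   \item \strong{serial}: fewer than 3 quadrant crosses, a sequential
#'     hole-visit order, and not spatial;
#'   \item \strong{random}: everything else.
#' }
#' The trajectory is rotated into the canonical frame internally, so the
#' label is invariant under joint rotation of the path and the target.
#' Lift-entry trials are trimmed with [trim_lift_start()] before
#' classification so that micromovements on the lift scaffold are not
#' scored.  Probe trials are not classified (the rules are defined for
#' training trials).
#'
#' @param traj a [trajectory()].
#' @param spec an [arena_spec()].
#' @param trim_threshold release radius passed to [trim_lift_start()] for
#'   LIFT trials; `NULL` skips trimming.
#' @return An object of class `strategy_label`: list with `label`
#'   (`"spatial"`, `"serial"`, `"random"`, or `NA` for unclassifiable
#'   trials), `n_quadrant_crosses`, `n_errors`, `visit_sequence`,
#'   `sequential`.
#' @export
classify_trial <- function(traj, spec, trim_threshold = 38) {
  stopifnot(inherits(traj, "maz_trajectory"), inherits(spec, "arena_spec"))
  out <- structure(
    list(label = NA_character_, n_quadrant_crosses = NA_integer_,
         n_errors = NA_integer_, visit_sequence = integer(0),
         sequential = NA),
    class = "strategy_label"
  )
  if (traj$phase != "training") {
    return(out)
  }
  work <- traj
  if (traj$entry == "LIFT" && !is.null(trim_threshold)) {
    work <- trim_lift_start(work, spec, trim_threshold)
  }
  if (work$invalid || n_frames(work) < 2) {
    return(out)
  }
  ct <- canonical_transform(work, spec)
  spec0 <- canonical_spec(spec)
  crosses <- quadrant_cross_count(ct, spec0)
  ev <- hole_visit_events(ct, spec0)
  errors <- sum(ev$hole != spec0$target_index)
  seqflag <- is_sequential(ev$hole, spec0$n_holes)
  label <- if (crosses == 0L && errors < 3L) {
    "spatial"
  } else if (crosses < 3L && seqflag) {
    "serial"
  } else {
    "random"
  }
  out$label <- label
  out$n_quadrant_crosses <- crosses
  out$n_errors <- as.integer(errors)
  out$visit_sequence <- ev$hole
  out$sequential <- seqflag
  out
}

#' @export
print.strategy_label <- function(x, ...) {
  cat(sprintf(
    "<strategy_label> %s (crosses %s, errors %s, sequential %s)\n",
    x$label, x$n_quadrant_crosses, x$n_errors, x$sequential
  ))
  invisible(x)
}

#' Daily strategy usage
#'
#' Per-subject-day counts of each strategy label and, aggregated over a
#' grouping column, per-day proportions normalised so that the three
#' strategy shares sum to 1 on each day.
#'
#' @param labels data.frame with columns `subject_id`, `day`, `label`, and
#'   optionally a grouping column (e.g. `entry`).
#' @param group_col optional column name for group-level proportions.
#' @return list with `counts` (subject x day strategy counts) and, when
#'   `group_col` is given, `proportions` (group x day shares).
#' @export
daily_strategy_usage <- function(labels, group_col = NULL) {
  stopifnot(all(c("subject_id", "day", "label") %in% names(labels)))
  lv <- c("spatial", "serial", "random")
  lab <- factor(labels$label, levels = lv)
  counts <- as.data.frame.matrix(
    table(paste(labels$subject_id, labels$day, sep = "\r"), lab)
  )
  key <- strsplit(rownames(counts), "\r", fixed = TRUE)
  counts <- cbind(
    data.frame(subject_id = vapply(key, `[`, character(1), 1),
               day = as.integer(vapply(key, `[`, character(1), 2))),
    counts
  )
  rownames(counts) <- NULL
  counts <- counts[order(counts$subject_id, counts$day), ]
  out <- list(counts = counts)
  if (!is.null(group_col)) {
    stopifnot(group_col %in% names(labels))
    tab <- table(
      group = labels[[group_col]], day = labels$day, label = lab
    )
    props <- as.data.frame(tab, responseName = "n")
    tot <- stats::aggregate(list(total = props$n),
                            props[c("group", "day")], FUN = sum)
    props <- merge(props, tot, by = c("group", "day"))
    props$proportion <- ifelse(props$total > 0, props$n / props$total, NA)
    props$day <- as.integer(as.character(props$day))
    out$proportions <- props[order(props$group, props$day, props$label),
                             c("group", "day", "label", "n", "proportion")]
    rownames(out$proportions) <- NULL
  }
  out
}
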