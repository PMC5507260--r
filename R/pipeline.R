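#' Full feature extraction for one trial
#'
#' Runs the whole analysis chain on a single trial: canonical rotation,
#' conventional features, the strategy label, the dynamic (stop/CCA)
#' network and its eight features, and the static (zone) network and its
#' features.  Conventional features are computed on the untrimmed
#' trajectory (latency is referenced to the trial start); strategy
#' classification and both networks use the lift-trimmed trajectory for
#' LIFT trials so that scaffold micromovements are not scored.
#'
#' @param traj a [trajectory()].
#' @param spec an [arena_spec()].
#' @param layout a [default_static_layout()]; computed from `spec` when
#'   `NULL` (pass one explicitly when processing many trials).
#' @param trim_threshold release radius for [trim_lift_start()].
#' @return A one-row data.frame: trial descriptors, conventional features,
#'   `strategy`, `n_quadrant_crosses`, dynamic-network features prefixed
#'   `dyn_`, static-network features prefixed `stat_`.
#' @export
trial_features <- function(traj, spec, layout = NULL, trim_threshold = 38) {
  stopifnot(inherits(traj, "maz_trajectory"), inherits(spec, "arena_spec"))
  if (is.null(layout)) layout <- default_static_layout(spec)
  ct <- canonical_transform(traj, spec)
  spec0 <- canonical_spec(spec)
  conv <- conventional_features(ct, spec0)
  lab <- classify_trial(traj, spec, trim_threshold)
  work <- ct
  if (traj$entry == "LIFT" && !is.null(trim_threshold)) {
    work <- trim_lift_start(ct, spec0, trim_threshold)
  }
  if (work$invalid || n_frames(work) < 2) work <- ct
  stops <- detect_stops(work, spec0)
  dyn <- net_features(build_local_network(stops, spec0))
  stat <- net_features(
    build_static_network(node_sequence(work, layout), layout,
                         positions = traj_xy(work))
  )
  names(dyn) <- paste0("dyn_", names(dyn))
  names(stat) <- paste0("stat_", names(stat))
  cbind(
    data.frame(subject_id = traj$subject_id, day = traj$day,
               trial = traj$trial, entry = traj$entry, phase = traj$phase,
               stringsAsFactors = FALSE),
    conv,
    data.frame(strategy = lab$label,
               n_quadrant_crosses = lab$n_quadrant_crosses,
               stringsAsFactors = FALSE),
    dyn, stat
  )
}

#' Feature table for a whole trial set
#'
#' Applies [trial_features()] to every trial and binds the rows.
#'
#' @param ts a [trial_set()].
#' @param layout optional shared [default_static_layout()].
#' @param trim_threshold release radius for [trim_lift_start()].
#' @return data.frame, one row per trial.
#' @export
cohort_features <- function(ts, layout = NULL, trim_threshold = 38) {
  stopifnot(inherits(ts, "maz_trial_set"))
  if (is.null(layout)) layout <- default_static_layout(ts$spec)
  do.call(rbind, lapply(ts$trials, trial_features, spec = ts$spec,
                        layout = layout, trim_threshold = trim_threshold))
}

#' Per-group-day global networks from a trial set
#'
#' Builds each trial's dynamic local network, then aggregates the local
#' networks of every (group, day) cell into a global network with
#' [build_global()].
#'
#' @param ts a [trial_set()].
#' @param group_col metadata field used as the grouping key (`"entry"` by
#'   default).
#' @param trim_threshold release radius for [trim_lift_start()].
#' @return named list of `behavior_network` objects of kind `"global"`,
#'   keyed `"<group>/day<day>"`.
#' @export
global_networks_by_day <- function(ts, group_col = "entry",
                                   trim_threshold = 38) {
  stopifnot(inherits(ts, "maz_trial_set"))
  spec0 <- canonical_spec(ts$spec)
  keys <- vapply(ts$trials, function(tr) {
    paste0(tr[[group_col]], "/day", tr$day)
  }, character(1))
  out <- list()
  for (key in unique(keys)) {
    trials <- ts$trials[keys == key]
    locals <- lapply(trials, function(tr) {
      ct <- canonical_transform(tr, ts$spec)
      if (tr$entry == "LIFT" && !is.null(trim_threshold)) {
        tct <- trim_lift_start(ct, spec0, trim_threshold)
        if (!tct$invalid && n_frames(tct) >= 2) ct <- tct
      }
      build_local_network(detect_stops(ct, spec0), spec0)
    })
    locals <- Filter(function(ln) nrow(ln$nodes) > 0, locals)
    if (length(locals) == 0) next
    first <- trials[[1]]
    out[[key]] <- build_global(locals, spec0,
                               group = as.character(first[[group_col]]),
                               day = first$day)
  }
  out
}
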