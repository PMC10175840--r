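#' Stimulus-locked analysis windows for a protocol
#'
#' The study's windows, anchored at pulse onset: `stimulus` is the whole
#' pulse, `early` its first 20 s, `late` the 20 s starting 30 s after
#' onset, `baseline` the pre-pulse period. For air-control protocols the
#' same clock times apply (matched windows).
#'
#' @param protocol A `stimulus_protocol`.
#' @return Named list of half-open `(start_s, end_s)` windows.
#' @export
analysis_windows <- function(protocol) {
  on <- pulse_onset(protocol)
  off <- pulse_offset(protocol)
  list(
    baseline = c(0, on),
    stimulus = c(on, off),
    early = c(on, on + 20),
    late = c(on + 30, on + 50)
  )
}

#' Per-animal behavior metrics and cohort speed summaries
#'
#' For each trajectory: mean speed in the early and late stimulus-locked
#' windows and at baseline; forward/reverse/pause time ratios over the
#' stimulus window and the baseline window; straight-line distance and
#' distance traveled in reverse over the stimulus window. Also returns
#' framewise group-mean +/- SEM speed traces per (group, condition).
#'
#' Animals recorded under an air-control protocol are analyzed over the
#' same clock-time windows (the matched air-control windows), with the
#' condition column distinguishing `"CO2"` from `"air"`.
#'
#' @param trajectories Non-empty list of `trajectory` objects sharing
#'   protocol timing.
#' @param smooth_s Speed smoothing, seconds (default 1).
#' @param pause_speed_mm_s,min_bout_s,reversal_angle_deg Segmentation
#'   parameters, see [segment_states()].
#' @return A `behavior_cohort` list with `per_animal` (one row per animal)
#'   and `speed_summary` (group, condition, t_s, mean, sem).
#' @export
behavior_cohort_table <- function(trajectories, smooth_s = 1,
                                  pause_speed_mm_s = 0.02, min_bout_s = 0.6,
                                  reversal_angle_deg = 120) {
  if (!is.list(trajectories) || length(trajectories) == 0)
    abort_invalid("`trajectories` must be a non-empty list")
  p0 <- trajectories[[1]]$protocol
  for (tr in trajectories[-1])
    if (!same_timing(tr$protocol, p0))
      abort_invalid("all trajectories must share the same protocol timing")
  rows <- vector("list", length(trajectories))
  speeds <- vector("list", length(trajectories))
  for (i in seq_along(trajectories)) {
    traj <- trajectories[[i]]
    w <- analysis_windows(traj$protocol)
    cond <- if (is_air_control(traj$protocol)) "air" else "CO2"
    st <- instantaneous_speed(traj, smooth_s = smooth_s)
    seg <- segment_states(traj, pause_speed_mm_s = pause_speed_mm_s,
                          min_bout_s = min_bout_s,
                          reversal_angle_deg = reversal_angle_deg)
    stim <- state_time_ratios(seg, w$stimulus)
    base <- state_time_ratios(seg, w$baseline)
    rows[[i]] <- data.frame(
      animal_id = traj$animal_id, group = traj$group, condition = cond,
      speed_baseline = mean_speed_in_window(st, w$baseline),
      speed_early = mean_speed_in_window(st, w$early),
      speed_late = mean_speed_in_window(st, w$late),
      forward_ratio = stim[["forward_ratio"]],
      reverse_ratio = stim[["reverse_ratio"]],
      pause_ratio = stim[["pause_ratio"]],
      forward_ratio_baseline = base[["forward_ratio"]],
      reverse_ratio_baseline = base[["reverse_ratio"]],
      pause_ratio_baseline = base[["pause_ratio"]],
      straight_line_mm = straight_line_distance(traj, w$stimulus),
      reverse_distance_mm = reverse_distance(traj, seg, w$stimulus),
      stringsAsFactors = FALSE
    )
    speeds[[i]] <- st$speed_mm_s
  }
  per_animal <- do.call(rbind, rows)
  key <- paste(per_animal$group, per_animal$condition, sep = "\r")
  t_s <- instantaneous_speed(trajectories[[1]], smooth_s = smooth_s)$t_s
  summ <- lapply(unique(key), function(k) {
    sel <- which(key == k)
    m <- do.call(rbind, speeds[sel])
    data.frame(
      group = per_animal$group[sel[1]],
      condition = per_animal$condition[sel[1]],
      t_s = t_s,
      mean_mm_s = colMeans(m),
      sem_mm_s = if (nrow(m) > 1) apply(m, 2, stats::sd) / sqrt(nrow(m))
                 else rep(0, ncol(m)),
      stringsAsFactors = FALSE
    )
  })
  structure(
    list(per_animal = per_animal, speed_summary = do.call(rbind, summ)),
    class = "behavior_cohort"
  )
}

#' @export
print.behavior_cohort <- function(x, ...) {
  agg <- stats::aggregate(
    x$per_animal[, c("speed_early", "speed_late", "pause_ratio")],
    by = list(group = x$per_animal$group, condition = x$per_animal$condition),
    FUN = mean
  )
  cat(sprintf("Behavior cohort: %d animals\n", nrow(x$per_animal)))
  print(agg, row.names = FALSE)
  invisible(x)
}
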