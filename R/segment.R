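#' Segment a trajectory into forward / reverse / pause states
#'
#' Centroid-level state segmentation. Each frame's displacement step (the
#' step ending at that frame) is classified: speed below
#' `pause_speed_mm_s` is a pause; moving frames start as forward and toggle
#' forward/reverse whenever the heading deviates by more than
#' `reversal_angle_deg` from a smoothed reference heading of the current
#' bout (a reversal flips the direction of travel by about 180 degrees).
#' After a toggle the reference resets to the current heading; within a
#' bout it tracks the heading as an exponential moving average so gradual
#' curving is not mistaken for a reversal. Bouts shorter than `min_bout_s`
#' are merged into their longer neighbor (shortest first, earlier bout on
#' ties) until none remain.
#'
#' Step k (the displacement between fenceposts k and k+1) covers the
#' half-open interval `[t_k, t_k + 1/frame_rate)`, so the labels tile
#' `[0, duration)` exactly.
#'
#' @param traj A `trajectory`.
#' @param pause_speed_mm_s Pause threshold, mm/s (default 0.02).
#' @param min_bout_s Minimum bout duration, seconds (default 0.6).
#' @param reversal_angle_deg Heading-change threshold for a reversal,
#'   degrees (default 120).
#' @param heading_alpha EMA weight for the within-bout reference heading
#'   (default 0.25).
#' @return A `state_segmentation`: `intervals` (contiguous,
#'   non-overlapping `(start_s, end_s, state)` rows with no two adjacent
#'   intervals sharing a state) plus the per-step `frame_states`.
#' @export
segment_states <- function(traj, pause_speed_mm_s = 0.02, min_bout_s = 0.6,
                           reversal_angle_deg = 120, heading_alpha = 0.25) {
  stopifnot(inherits(traj, "trajectory"))
  check_number(pause_speed_mm_s, "pause_speed_mm_s", strict_min = 0)
  check_number(min_bout_s, "min_bout_s", strict_min = 0)
  check_number(reversal_angle_deg, "reversal_angle_deg", strict_min = 0)
  n <- length(traj$t_s)
  if (n < 3) abort_invalid("at least 3 frames are required")
  dt <- 1 / traj$protocol$frame_rate
  dx <- diff(traj$x_mm)
  dy <- diff(traj$y_mm)
  speed <- sqrt(dx^2 + dy^2) / dt
  heading <- atan2(dy, dx)
  labels <- classify_steps(speed, heading, pause_speed_mm_s,
                           reversal_angle_deg * pi / 180, heading_alpha)
  frame_states <- merge_short_bouts(labels, dt, min_bout_s)
  intervals <- states_to_intervals(frame_states, dt)
  structure(
    list(intervals = intervals,
         frame_states = factor(frame_states, levels = STATES),
         t_s = traj$t_s, frame_rate = traj$protocol$frame_rate),
    class = "state_segmentation"
  )
}

# Per-step classification; steps are displacement intervals ending at
# frames 2..n. Direction state persists across pauses.
classify_steps <- function(speed, heading, pause_thr, angle_thr, alpha) {
  m <- length(speed)
  labels <- character(m)
  dir_forward <- TRUE
  ref <- NA_real_
  for (i in seq_len(m)) {
    if (speed[i] < pause_thr) {
      labels[i] <- "pause"
      next
    }
    h <- heading[i]
    if (is.na(ref)) {
      ref <- h
    } else if (abs(ang_diff(h, ref)) > angle_thr) {
      dir_forward <- !dir_forward
      ref <- h
    } else {
      ref <- ref + alpha * ang_diff(h, ref)
    }
    labels[i] <- if (dir_forward) "forward" else "reverse"
  }
  labels
}

# Iteratively absorb bouts shorter than min_bout_s into the longer
# neighbor: shortest bout first (earlier on ties); prefer the previous
# neighbor on duration ties.
merge_short_bouts <- function(frame_states, dt, min_bout_s) {
  repeat {
    r <- rle(frame_states)
    if (length(r$lengths) <= 1) break
    durs <- r$lengths * dt
    short <- which(durs < min_bout_s - 1e-9)
    if (length(short) == 0) break
    j <- short[which.min(durs[short])]
    nb <- c(if (j > 1) j - 1L, if (j < length(durs)) j + 1L)
    take <- nb[which.max(durs[nb])]
    r$values[j] <- r$values[take]
    frame_states <- inverse.rle(r)
  }
  frame_states
}

states_to_intervals <- function(frame_states, dt) {
  r <- rle(frame_states)
  ends <- cumsum(r$lengths) * dt
  starts <- c(0, ends[-length(ends)])
  data.frame(start_s = starts, end_s = ends, state = r$values,
             stringsAsFactors = FALSE)
}

#' @export
print.state_segmentation <- function(x, ...) {
  cat(sprintf("State segmentation: %d intervals over [0, %g) s\n",
              nrow(x$intervals), max(x$intervals$end_s)))
  print(x$intervals, row.names = FALSE)
  invisible(x)
}

# State label covering time t (frame grid lookup).
state_at <- function(seg, t) {
  i <- findInterval(t, seg$intervals$start_s)
  i[i < 1] <- NA_integer_
  out <- seg$intervals$state[i]
  out[t >= max(seg$intervals$end_s)] <- NA_character_
  out
}

#' Forward / reverse / pause time ratios over a window
#'
#' Fraction of the window spent in each state. The three ratios partition
#' the window and sum to exactly 1 (the pause ratio is computed as the
#' complement).
#'
#' @param seg A `state_segmentation`.
#' @param window `(start_s, end_s)`, half-open, within the analyzed span.
#' @return Named numeric `c(forward_ratio, reverse_ratio, pause_ratio)`.
#' @export
state_time_ratios <- function(seg, window) {
  stopifnot(inherits(seg, "state_segmentation"))
  check_window(window)
  span <- c(min(seg$intervals$start_s), max(seg$intervals$end_s))
  if (window[1] < span[1] - 1e-9 || window[2] > span[2] + 1e-9)
    abort_invalid("`window` must lie within the analyzed span")
  overlap <- function(state) {
    sel <- seg$intervals$state == state
    sum(pmax(0, pmin(seg$intervals$end_s[sel], window[2]) -
               pmax(seg$intervals$start_s[sel], window[1])))
  }
  len <- window[2] - window[1]
  fwd <- overlap("forward") / len
  rev <- overlap("reverse") / len
  # Fast2Sum compensation: nudge the smaller of the two ratios by <= 1 ulp
  # and take pause as the complement, so forward + reverse + pause == 1
  # exactly (even under long-double accumulation in sum())
  a <- max(fwd, rev); b <- min(fwd, rev)
  s2 <- min(a + b, 1)
  b <- s2 - a  # exact since |a| >= |b|
  if (fwd < rev) { fwd <- b; rev <- a } else { fwd <- a; rev <- b }
  c(forward_ratio = fwd, reverse_ratio = rev, pause_ratio = 1 - s2)
}

#' Distance traveled in reverse over a window
#'
#' Sum of framewise displacement magnitudes over steps labeled reverse
#' whose covering intervals start in the half-open window.
#'
#' @param traj A `trajectory`.
#' @param seg Its `state_segmentation`.
#' @param window `(start_s, end_s)`, half-open.
#' @return Distance, mm.
#' @export
reverse_distance <- function(traj, seg, window) {
  stopifnot(inherits(traj, "trajectory"), inherits(seg, "state_segmentation"))
  check_window(window)
  disp <- sqrt(diff(traj$x_mm)^2 + diff(traj$y_mm)^2)
  t_step <- traj$t_s[-length(traj$t_s)]
  sel <- in_window(t_step, window) & as.character(seg$frame_states) == "reverse"
  sum(disp[sel])
}
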