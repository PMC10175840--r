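#' Instantaneous speed from a centroid trajectory
#'
#' Framewise displacement magnitude divided by the frame interval, with the
#' speed sample assigned to the later frame of each displacement pair, and
#' optional centered moving-average smoothing (edge samples use truncated
#' windows, so a constant speed is a fixed point of the smoother).
#'
#' @param traj A `trajectory`.
#' @param smooth_s Smoothing window length, seconds (0 disables; default 1).
#' @return A `speed_trace` data frame with `t_s` and `speed_mm_s`
#'   (length = frames - 1).
#' @export
instantaneous_speed <- function(traj, smooth_s = 1) {
  stopifnot(inherits(traj, "trajectory"))
  check_number(smooth_s, "smooth_s", min = 0)
  if (length(traj$t_s) < 2)
    abort_invalid("at least 2 frames are required")
  dt <- diff(traj$t_s)
  sp <- sqrt(diff(traj$x_mm)^2 + diff(traj$y_mm)^2) / dt
  if (smooth_s > 0) {
    half <- floor(smooth_s * traj$protocol$frame_rate / 2)
    if (half > 0) sp <- truncated_running_mean(sp, half)
  }
  structure(
    data.frame(t_s = traj$t_s[-1], speed_mm_s = sp),
    class = c("speed_trace", "data.frame")
  )
}

# Centered running mean over window [i-half, i+half], truncated at edges.
truncated_running_mean <- function(x, half) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Mean speed over an analysis window
#'
#' Arithmetic mean of speed samples whose timestamps fall in the half-open
#' window. The study's stimulus-locked windows are the first 20 s of the
#' pulse, `[onset, onset + 20)`, and a later window `[onset + 30,
#' onset + 50)`.
#'
#' @param st A `speed_trace`.
#' @param window `(start_s, end_s)`, half-open.
#' @return Mean speed, mm/s.
#' @export
mean_speed_in_window <- function(st, window) {
  check_window(window)
  sel <- in_window(st$t_s, window)
  if (!any(sel))
    abort_invalid("`window` contains no speed samples")
  mean(st$speed_mm_s[sel])
}

#' Straight-line (net) displacement over a window
#'
#' Euclidean distance between the first and last positions whose timestamps
#' fall in the half-open window. Always bounded above by the path length
#' over the same frames.
#'
#' @param traj A `trajectory`.
#' @param window `(start_s, end_s)`, half-open.
#' @return Distance, mm.
#' @export
straight_line_distance <- function(traj, window) {
  stopifnot(inherits(traj, "trajectory"))
  check_window(window)
  sel <- which(in_window(traj$t_s, window))
  if (length(sel) < 2)
    abort_invalid("`window` must contain at least 2 frames")
  i <- sel[1]; j <- sel[length(sel)]
  sqrt((traj$x_mm[j] - traj$x_mm[i])^2 + (traj$y_mm[j] - traj$y_mm[i])^2)
}
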