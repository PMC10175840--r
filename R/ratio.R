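#' Convert a two-channel recording to a percent dR/R0 ratio trace
#'
#' Computes the framewise acceptor/donor ratio `r`, the baseline ratio `r0`
#' as the mean of `r` over `baseline_window` (half-open, pre-pulse), and the
#' fractional change `dr_pct = 100 * (r - r0) / r0`. dR/R0 is invariant to
#' any common positive rescaling of the two channels, which is the point of
#' ratiometric imaging: shared gain and bleaching cancel.
#'
#' @param trace A `calcium_trace`.
#' @param baseline_window `(start_s, end_s)`, half-open, inside the
#'   recording and ending no later than pulse onset, with at least 2 frames.
#'   Default: the pre-pulse segment minus its first 2 s (settling).
#' @return A `ratio_trace` aligned frame-for-frame with the input, carrying
#'   `t_s`, `r`, `r0`, `dr_pct` and the input's identifiers and protocol.
#' @export
compute_ratio_trace <- function(trace, baseline_window = NULL) {
  stopifnot(inherits(trace, "calcium_trace"))
  onset <- pulse_onset(trace$protocol)
  if (is.null(baseline_window))
    baseline_window <- c(min(2, onset / 2), onset)
  check_window(baseline_window, "baseline_window")
  t <- trace$t_s
  if (baseline_window[1] < t[1] - 1e-9 ||
      baseline_window[2] > protocol_duration(trace$protocol) + 1e-9)
    abort_invalid("`baseline_window` must lie inside the recording")
  if (baseline_window[2] > onset + 1e-9)
    abort_invalid("`baseline_window` must end at or before pulse onset")
  if (any(trace$donor <= 0) || any(trace$acceptor <= 0))
    abort_data("fluorescence channels must be positive at every frame")
  sel <- in_window(t, baseline_window)
  if (sum(sel) < 2)
    abort_invalid("`baseline_window` must contain at least 2 frames")
  r <- trace$acceptor / trace$donor
  r0 <- mean(r[sel])
  structure(
    list(animal_id = trace$animal_id, neuron = trace$neuron,
         group = trace$group, t_s = t, r = r, r0 = r0,
         dr_pct = 100 * (r - r0) / r0, protocol = trace$protocol),
    class = "ratio_trace"
  )
}

#' @export
print.ratio_trace <- function(x, ...) {
  cat(sprintf("Ratio trace %s (%s, %s): r0 = %.3f, dR/R0 range [%.1f, %.1f]%%\n",
              x$animal_id, x$neuron, x$group, x$r0, min(x$dr_pct),
              max(x$dr_pct)))
  invisible(x)
}

# Default response window: pulse onset to 30 s past offset (captures
# post-offset responses), clipped to the recording.
default_response_window <- function(protocol) {
  c(pulse_onset(protocol),
    min(pulse_offset(protocol) + 30, protocol_duration(protocol)))
}

#' Maximum and minimum dR/R0 over a response window
#'
#' Extrema of `dr_pct` over frames whose timestamps fall in the half-open
#' window `[start_s, end_s)`.
#'
#' @param rt A `ratio_trace`.
#' @param response_window `(start_s, end_s)`; default pulse onset to 30 s
#'   past pulse offset, clipped to the recording.
#' @return Named numeric `c(max_pct, min_pct)`.
#' @export
peak_amplitudes <- function(rt, response_window = NULL) {
  stopifnot(inherits(rt, "ratio_trace"))
  if (is.null(response_window))
    response_window <- default_response_window(rt$protocol)
  check_window(response_window, "response_window")
  sel <- in_window(rt$t_s, response_window)
  if (!any(sel))
    abort_invalid("`response_window` contains no frames")
  v <- rt$dr_pct[sel]
  c(max_pct = max(v), min_pct = min(v))
}

# Signed extremum: the dr_pct value of largest magnitude in the window
# (first occurrence on magnitude ties).
extremum_stat <- function(rt, response_window) {
  sel <- in_window(rt$t_s, response_window)
  v <- rt$dr_pct[sel]
  v[which.max(abs(v))]
}
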