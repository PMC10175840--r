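#' Build a three-segment gas stimulus protocol
#'
#' Constructs the standard pulse protocol used throughout the package: a
#' pre-stimulus air segment, a gas pulse, and a post-stimulus air segment,
#' sampled at a fixed frame rate. An air-control protocol (the empirical
#' null condition, in which the pulse is replaced by air of equal duration)
#' is produced by `pulse_label = "air"`; the pulse timing is retained so
#' that matched analysis windows can be taken at identical clock times.
#'
#' @param pre_s Duration of the pre-stimulus air segment, seconds.
#' @param pulse_s Duration of the stimulus pulse, seconds.
#' @param post_s Duration of the post-stimulus air segment, seconds.
#' @param frame_rate Acquisition rate, frames per second.
#' @param pulse_label Gas label of the pulse segment, `"CO2"` or `"air"`.
#' @param pulse_composition Free-text composition tag for the pulse segment,
#'   e.g. `"15% CO2"` (imaging) or `"2.5% CO2, 21% O2, balance N2"`
#'   (behavior). Defaults to the pulse label.
#'
#' @return A `stimulus_protocol`: frame rate plus an ordered, contiguous
#'   segment table `(label, composition, start_s, end_s)` with half-open
#'   segments starting at 0.
#' @examples
#' p <- make_protocol(20, 60, 40, frame_rate = 5)
#' pulse_window(p)
#' @export
make_protocol <- function(pre_s, pulse_s, post_s, frame_rate,
                          pulse_label = "CO2",
                          pulse_composition = NULL) {
  check_number(pre_s, "pre_s", strict_min = 0)
  check_number(pulse_s, "pulse_s", strict_min = 0)
  check_number(post_s, "post_s", strict_min = 0)
  check_number(frame_rate, "frame_rate", strict_min = 0)
  if (!is.character(pulse_label) || length(pulse_label) != 1L ||
      !pulse_label %in% c("CO2", "air"))
    abort_invalid("`pulse_label` must be \"CO2\" or \"air\"")
  if (is.null(pulse_composition))
    pulse_composition <- if (pulse_label == "air") "air" else pulse_label
  segments <- data.frame(
    label = c("air", pulse_label, "air"),
    composition = c("air", pulse_composition, "air"),
    start_s = c(0, pre_s, pre_s + pulse_s),
    end_s = c(pre_s, pre_s + pulse_s, pre_s + pulse_s + post_s),
    stringsAsFactors = FALSE
  )
  structure(
    list(frame_rate = frame_rate, segments = segments, pulse_segment = 2L),
    class = "stimulus_protocol"
  )
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("Stimulus protocol: %g s at %g fps (%d frames)\n",
              protocol_duration(x), x$frame_rate, n_frames(x)))
  for (i in seq_len(nrow(x$segments))) {
    s <- x$segments[i, ]
    cat(sprintf("  [%g, %g) s  %-4s %s\n", s$start_s, s$end_s, s$label,
                s$composition))
  }
  invisible(x)
}

#' Protocol timing helpers
#'
#' `protocol_duration()` is the total recording length in seconds;
#' `n_frames()` the number of frames; `frame_times()` the frame timestamps
#' (frame i at `(i-1)/frame_rate`); `pulse_onset()`/`pulse_offset()` the
#' pulse segment boundaries (defined even for air-control protocols, so
#' matched windows can be placed at identical clock times);
#' `pulse_window()` the half-open `(onset, offset)` pair; `is_air_control()`
#' whether the pulse segment is air.
#'
#' @param protocol A `stimulus_protocol`.
#' @return A numeric scalar/vector as described, or logical for
#'   `is_air_control()`.
#' @export
protocol_duration <- function(protocol) {
  max(protocol$segments$end_s)
}

#' @rdname protocol_duration
#' @export
n_frames <- function(protocol) {
  as.integer(round(protocol_duration(protocol) * protocol$frame_rate))
}

#' @rdname protocol_duration
#' @export
frame_times <- function(protocol) {
  (seq_len(n_frames(protocol)) - 1) / protocol$frame_rate
}

#' @rdname protocol_duration
#' @export
pulse_onset <- function(protocol) {
  protocol$segments$start_s[protocol$pulse_segment]
}

#' @rdname protocol_duration
#' @export
pulse_offset <- function(protocol) {
  protocol$segments$end_s[protocol$pulse_segment]
}

#' @rdname protocol_duration
#' @export
pulse_window <- function(protocol) {
  c(pulse_onset(protocol), pulse_offset(protocol))
}

#' @rdname protocol_duration
#' @export
is_air_control <- function(protocol) {
  protocol$segments$label[protocol$pulse_segment] == "air"
}

# Two protocols share timing if frame rate and segment boundaries agree.
same_timing <- function(a, b) {
  isTRUE(all.equal(a$frame_rate, b$frame_rate)) &&
    nrow(a$segments) == nrow(b$segments) &&
    isTRUE(all.equal(a$segments$start_s, b$segments$start_s)) &&
    isTRUE(all.equal(a$segments$end_s, b$segments$end_s))
}
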