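#' Stimulus-response kernel for simulated calcium transients
#'
#' Unit-amplitude rise-and-decay bump: zero before `onset_s`, linear rise to
#' 1 over `rise_s`, then exponential decay with time constant `tau_s`. The
#' simulated acceptor/donor ratio follows
#' `baseline * (1 + sign * amplitude/100 * kernel(t))`.
#'
#' @param t Time points, seconds.
#' @param onset_s Response start time, seconds.
#' @param rise_s Linear rise time, seconds (default 3).
#' @param tau_s Exponential decay time constant, seconds (default 10).
#' @return Kernel values in `[0, 1]` at `t`.
#' @export
response_kernel <- function(t, onset_s, rise_s = 3, tau_s = 10) {
  check_number(rise_s, "rise_s", strict_min = 0)
  check_number(tau_s, "tau_s", strict_min = 0)
  dt <- t - onset_s
  k <- numeric(length(t))
  rising <- dt >= 0 & dt < rise_s
  decaying <- dt >= rise_s
  k[rising] <- dt[rising] / rise_s
  k[decaying] <- exp(-(dt[decaying] - rise_s) / tau_s)
  k
}

#' Ground-truth description of one simulated calcium response
#'
#' @param response_class `"excitatory"`, `"inhibitory"`, or `"silent"`.
#' @param amplitude_pct Peak response amplitude in percent dR/R0 units
#'   (non-negative; forced to 0 for silent responses).
#' @param onset_latency_s Latency of response start after the pulse onset
#'   (or after the pulse offset when `post_offset = TRUE`), seconds.
#' @param rise_s,decay_tau_s Kernel shape parameters, seconds.
#' @param post_offset If `TRUE` the response begins after pulse termination,
#'   as seen for the post-pulse inhibition of dauer RIG.
#' @return A `calcium_truth` list.
#' @export
calcium_truth <- function(response_class = c("excitatory", "inhibitory", "silent"),
                          amplitude_pct = 20, onset_latency_s = 2,
                          rise_s = 3, decay_tau_s = 10, post_offset = FALSE) {
  response_class <- match.arg(response_class)
  check_number(amplitude_pct, "amplitude_pct", min = 0)
  check_number(onset_latency_s, "onset_latency_s", min = 0)
  if (response_class == "silent") amplitude_pct <- 0
  structure(
    list(response_class = response_class, amplitude_pct = amplitude_pct,
         onset_latency_s = onset_latency_s, rise_s = rise_s,
         decay_tau_s = decay_tau_s, post_offset = isTRUE(post_offset)),
    class = "calcium_truth"
  )
}

new_calcium_trace <- function(animal_id, neuron, group, t_s, donor, acceptor,
                              protocol) {
  structure(
    list(animal_id = animal_id, neuron = neuron, group = group, t_s = t_s,
         donor = donor, acceptor = acceptor, protocol = protocol),
    class = "calcium_trace"
  )
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat(sprintf("Calcium trace %s (%s, %s): %d frames at %g fps\n",
              x$animal_id, x$neuron, x$group, length(x$t_s),
              x$protocol$frame_rate))
  invisible(x)
}

#' Simulate one two-channel ratiometric calcium recording
#'
#' Emulates a FRET-indicator recording (donor + acceptor channel) in which
#' the acceptor/donor ratio follows `r0 * (1 + s * A/100 * kernel(t))` with
#' `s = +1` for excitatory, `-1` for inhibitory, and `0` for silent
#' responses. The kernel starts at pulse onset plus latency (pulse offset
#' plus latency for post-offset responses). Both channels carry independent
#' multiplicative Gaussian noise and a shared exponential bleaching decay,
#' which the ratio cancels.
#'
#' @param protocol A `stimulus_protocol`.
#' @param truth A [calcium_truth()].
#' @param noise_sd Per-channel multiplicative noise SD, as a fraction of the
#'   signal (default 0.01).
#' @param bleach_rate Shared photobleaching rate, per second (default 0).
#' @param seed Optional integer seed; identical seeds give identical output.
#' @param r0 Baseline acceptor/donor ratio (default 1.5).
#' @param donor0 Baseline donor intensity, arbitrary units (default 100).
#' @param animal_id,neuron,group Identifiers attached to the trace.
#' @return A `calcium_trace` with positive `donor` and `acceptor` channels
#'   on the protocol's frame grid.
#' @export
simulate_calcium_trace <- function(protocol, truth, noise_sd = 0.01,
                                   bleach_rate = 0, seed = NULL,
                                   r0 = 1.5, donor0 = 100,
                                   animal_id = "a1", neuron = "BAG",
                                   group = "group") {
  stopifnot(inherits(protocol, "stimulus_protocol"),
            inherits(truth, "calcium_truth"))
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(bleach_rate, "bleach_rate", min = 0)
  check_number(r0, "r0", strict_min = 0)
  check_number(donor0, "donor0", strict_min = 0)
  t <- frame_times(protocol)
  sgn <- switch(truth$response_class, excitatory = 1, inhibitory = -1,
                silent = 0)
  start <- (if (truth$post_offset) pulse_offset(protocol) else
    pulse_onset(protocol)) + truth$onset_latency_s
  k <- response_kernel(t, start, truth$rise_s, truth$decay_tau_s)
  factor <- 1 + sgn * truth$amplitude_pct / 100 * k
  if (any(factor <= 0))
    abort_invalid("response amplitude would drive the ratio non-positive (inhibitory amplitude must be < 100%)")
  with_seed(seed, {
    bleach <- exp(-bleach_rate * t)
    donor <- donor0 * bleach * (1 + stats::rnorm(length(t), 0, noise_sd))
    acceptor <- donor0 * r0 * factor * bleach *
      (1 + stats::rnorm(length(t), 0, noise_sd))
    if (any(donor <= 0) || any(acceptor <= 0))
      abort_invalid("noise level drove a fluorescence channel non-positive; reduce `noise_sd`")
    new_calcium_trace(animal_id, neuron, group, t, donor, acceptor, protocol)
  })
}

draw_amplitude <- function(spec) {
  if (is.numeric(spec) && length(spec) == 1L) return(spec)
  kind <- spec$kind %||% "uniform"
  switch(kind,
    uniform = stats::runif(1, spec$min, spec$max),
    constant = spec$value,
    lognormal = stats::rlnorm(1, spec$meanlog, spec$sdlog),
    abort_invalid(sprintf("unknown amplitude distribution kind \"%s\"", kind))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a cohort of calcium recordings with known ground truth
#'
#' Draws each animal's response class i.i.d. from `class_mix`, its amplitude
#' from `amplitude_dist`, and simulates a recording. Each animal uses an
#' independent RNG stream derived deterministically from `(seed, index)`, so
#' cohorts are reproducible and individual animals re-simulable.
#'
#' @param protocol A `stimulus_protocol`.
#' @param class_mix Named probabilities over
#'   `c("excitatory", "inhibitory", "silent")`; must sum to 1.
#' @param amplitude_dist Amplitude distribution spec: a single number, or a
#'   list like `list(kind = "uniform", min = 20, max = 35)` (percent units).
#' @param n Number of animals.
#' @param seed Root seed for the cohort.
#' @param latency_range Uniform range for onset latency, seconds.
#' @param noise_sd,bleach_rate,neuron,group Passed to
#'   [simulate_calcium_trace()].
#' @param post_offset Logical: responses begin after pulse offset.
#' @param id_prefix Prefix for generated animal ids.
#' @return A list with `traces` (list of `calcium_trace`) and `truth`
#'   (data frame of per-animal ground truth).
#' @export
simulate_calcium_cohort <- function(protocol, class_mix, amplitude_dist =
                                      list(kind = "uniform", min = 20, max = 35),
                                    n, seed = 1,
                                    latency_range = c(1, 3),
                                    noise_sd = 0.01, bleach_rate = 0,
                                    neuron = "BAG", group = "group",
                                    post_offset = FALSE,
                                    id_prefix = group) {
  classes <- c("excitatory", "inhibitory", "silent")
  if (is.null(names(class_mix)) && length(class_mix) == 3L)
    names(class_mix) <- classes
  if (!all(names(class_mix) %in% classes) || length(class_mix) != 3L ||
      any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-8)
    abort_invalid("`class_mix` must be 3 non-negative probabilities over excitatory/inhibitory/silent summing to 1")
  class_mix <- class_mix[classes]
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    abort_invalid("`n` must be a positive integer")
  traces <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    cs <- child_seed(seed, i)
    tr <- with_seed(cs, {
      cls <- sample(classes, 1, prob = class_mix)
      amp <- if (cls == "silent") 0 else draw_amplitude(amplitude_dist)
      lat <- stats::runif(1, latency_range[1], latency_range[2])
      truth <- calcium_truth(cls, amp, onset_latency_s = lat,
                             post_offset = post_offset)
      trace <- simulate_calcium_trace(protocol, truth, noise_sd = noise_sd,
                                      bleach_rate = bleach_rate, seed = NULL,
                                      animal_id = sprintf("%s_%03d", id_prefix, i),
                                      neuron = neuron, group = group)
      list(truth = truth, trace = trace)
    })
    traces[[i]] <- tr$trace
    truth_rows[[i]] <- data.frame(
      animal_id = tr$trace$animal_id, group = group, neuron = neuron,
      response_class = tr$truth$response_class,
      amplitude_pct = tr$truth$amplitude_pct,
      onset_latency_s = tr$truth$onset_latency_s,
      post_offset = tr$truth$post_offset,
      stringsAsFactors = FALSE
    )
  }
  list(traces = traces, truth = do.call(rbind, truth_rows))
}
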