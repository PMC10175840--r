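STATES <- c("forward", "reverse", "pause")

#' Locomotion-simulator parameters
#'
#' Parameters for a three-state (forward/reverse/pause) continuous-time
#' Markov jump process with epoch-dependent transition rates: `baseline`
#' rates apply outside the stimulus, `stimulus` rates inside it. The
#' stimulus epoch is the pulse segment of the protocol, optionally truncated
#' after `adapt_s` seconds (behavioral adaptation: rates revert to baseline
#' while the gas is still on) and optionally extended `carry_over_s` seconds
#' past pulse offset (persistent response).
#'
#' @param baseline,stimulus 3x3 transition-rate matrices (per second) with
#'   rows/columns ordered forward, reverse, pause; diagonals are ignored.
#' @param speed_mean,speed_sd Per-state translocation speed mean and SD,
#'   mm/s, ordered as above. Pause speed should be near 0.
#' @param heading_diffusion Heading diffusion coefficient, radians^2/s.
#' @param frame_rate Frames per second.
#' @param adapt_s Seconds after pulse onset at which stimulus rates revert
#'   to baseline (default `Inf`: the whole pulse).
#' @param carry_over_s Seconds past pulse offset during which stimulus rates
#'   persist (default 0).
#' @param jitter_mm Per-frame isotropic positional noise SD, mm (default 0).
#' @param init_state Initial behavioral state.
#' @param init_heading Initial heading, radians, or `NULL` to draw uniformly.
#' @return A `locomotion_params` list.
#' @export
locomotion_params <- function(baseline, stimulus = baseline,
                              speed_mean = c(forward = 0.15, reverse = 0.12,
                                             pause = 0.005),
                              speed_sd = c(forward = 0.03, reverse = 0.03,
                                           pause = 0.002),
                              heading_diffusion = 0.1,
                              frame_rate = 5,
                              adapt_s = Inf, carry_over_s = 0,
                              jitter_mm = 0,
                              init_state = "forward",
                              init_heading = NULL) {
  check_rates <- function(m, name) {
    if (!is.matrix(m) || !all(dim(m) == c(3, 3)) || any(m[row(m) != col(m)] < 0))
      abort_invalid(sprintf("`%s` must be a 3x3 matrix of non-negative rates", name))
    dimnames(m) <- list(STATES, STATES)
    diag(m) <- 0
    m
  }
  baseline <- check_rates(baseline, "baseline")
  stimulus <- check_rates(stimulus, "stimulus")
  if (length(speed_mean) != 3L || any(speed_mean < 0))
    abort_invalid("`speed_mean` must be 3 non-negative speeds (mm/s)")
  if (length(speed_sd) != 3L || any(speed_sd < 0))
    abort_invalid("`speed_sd` must be 3 non-negative SDs (mm/s)")
  check_number(heading_diffusion, "heading_diffusion", min = 0)
  check_number(frame_rate, "frame_rate", strict_min = 0)
  check_number(carry_over_s, "carry_over_s", min = 0)
  check_number(jitter_mm, "jitter_mm", min = 0)
  if (!init_state %in% STATES)
    abort_invalid("`init_state` must be forward, reverse, or pause")
  structure(
    list(baseline = baseline, stimulus = stimulus,
         speed_mean = stats::setNames(as.numeric(speed_mean), STATES),
         speed_sd = stats::setNames(as.numeric(speed_sd), STATES),
         heading_diffusion = heading_diffusion, frame_rate = frame_rate,
         adapt_s = adapt_s, carry_over_s = carry_over_s,
         jitter_mm = jitter_mm, init_state = init_state,
         init_heading = init_heading),
    class = "locomotion_params"
  )
}

rate_matrix <- function(fr = 0.05, fp = 0.02, rf = 0.5, rp = 0.05,
                        pf = 0.3, pr = 0.05) {
  m <- matrix(0, 3, 3, dimnames = list(STATES, STATES))
  m["forward", "reverse"] <- fr; m["forward", "pause"] <- fp
  m["reverse", "forward"] <- rf; m["reverse", "pause"] <- rp
  m["pause", "forward"] <- pf; m["pause", "reverse"] <- pr
  m
}

#' Preset locomotion parameter sets
#'
#' Two generator presets expressing the qualitative life-stage contrast in
#' CO2-evoked slowing: `"dauer_like"` strongly elevates pause entry for the
#' whole pulse (prolonged near-arrest), `"adult_like"` elevates reversal and
#' pause rates only for the first 20 s of the pulse (`adapt_s = 20`), giving
#' a transient slowdown. `"air"` variants are not needed: an air-control
#' protocol simply never enters the stimulus epoch.
#'
#' @param which Preset name.
#' @param frame_rate Frames per second (default 5).
#' @return A [locomotion_params()] object.
#' @export
locomotion_preset <- function(which = c("dauer_like", "adult_like"),
                              frame_rate = 5) {
  which <- match.arg(which)
  base <- rate_matrix()
  switch(which,
    dauer_like = locomotion_params(
      baseline = base,
      stimulus = rate_matrix(fr = 0.15, fp = 0.6, rf = 0.2, rp = 0.4,
                             pf = 0.02, pr = 0.02),
      frame_rate = frame_rate
    ),
    adult_like = locomotion_params(
      baseline = base,
      stimulus = rate_matrix(fr = 0.35, fp = 0.25, rf = 0.35, rp = 0.1,
                             pf = 0.12, pr = 0.1),
      adapt_s = 20,
      frame_rate = frame_rate
    )
  )
}

# Piecewise-constant stimulus epoch: [onset, min(onset+adapt, offset+carry)).
stimulus_epoch <- function(protocol, params) {
  if (is_air_control(protocol)) return(NULL)
  on <- pulse_onset(protocol)
  off <- min(on + params$adapt_s, pulse_offset(protocol) + params$carry_over_s)
  if (off <= on) return(NULL)
  c(on, off)
}

# Position fenceposts: a recording of N frame intervals has N + 1 position
# samples at k/frame_rate, k = 0..N, so the N displacement steps tile
# [0, duration) exactly; step k covers [t_k, t_{k+1}) and is governed by
# the behavioral state at its start.

# Exact CTMC simulation over piecewise-constant rate epochs. Returns jump
# times and the state holding from each time. Memorylessness lets us
# re-sample the exponential clock at every epoch boundary.
simulate_ctmc <- function(total_s, boundaries, rates_at, init_state) {
  times <- 0
  states <- init_state
  t <- 0
  s <- init_state
  bnd <- sort(unique(c(boundaries, total_s)))
  bnd <- bnd[bnd > 0 & bnd <= total_s]
  bi <- 1L
  while (t < total_s) {
    tb <- bnd[bi]
    Q <- rates_at(t)
    lambda <- sum(Q[s, ])
    dt <- if (lambda > 0) stats::rexp(1, lambda) else Inf
    if (t + dt < tb) {
      t <- t + dt
      s <- sample(STATES, 1, prob = Q[s, ])
      times <- c(times, t)
      states <- c(states, s)
    } else {
      t <- tb
      bi <- bi + 1L
      if (bi > length(bnd)) break
    }
  }
  list(times = times, states = states)
}

new_trajectory <- function(animal_id, group, t_s, x_mm, y_mm, protocol) {
  structure(
    list(animal_id = animal_id, group = group, t_s = t_s, x_mm = x_mm,
         y_mm = y_mm, protocol = protocol),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory %s (%s): %d frames at %g fps, span %.2f x %.2f mm\n",
              x$animal_id, x$group, length(x$t_s), x$protocol$frame_rate,
              diff(range(x$x_mm)), diff(range(x$y_mm))))
  invisible(x)
}

#' Simulate a centroid locomotion trajectory with ground-truth states
#'
#' Runs a continuous-time Markov jump process over forward/reverse/pause
#' with epoch-appropriate rates (see [locomotion_params()]), then integrates
#' position: heading performs a diffusion, per-step speed is drawn from the
#' current state's speed distribution (truncated at 0), and reversal flips
#' the effective heading by pi. The trajectory carries `n_frames + 1`
#' position fenceposts so its `n_frames` displacement steps tile
#' `[0, duration)`; each step is governed by the state at its start.
#'
#' @param protocol A `stimulus_protocol`.
#' @param params A [locomotion_params()].
#' @param seed Optional seed; identical seeds give identical output.
#' @param animal_id,group Identifiers.
#' @return A list with `trajectory` (a `trajectory`), `states` (ground-truth
#'   per-step state factor, aligned with [segment_states()] labels), and
#'   `jumps` (continuous-time jump record, for dwell-time diagnostics).
#' @export
simulate_trajectory <- function(protocol, params, seed = NULL,
                                animal_id = "w1", group = "group") {
  stopifnot(inherits(protocol, "stimulus_protocol"),
            inherits(params, "locomotion_params"))
  if (!isTRUE(all.equal(params$frame_rate, protocol$frame_rate)))
    abort_invalid("`params$frame_rate` must match the protocol frame rate")
  total <- protocol_duration(protocol)
  epoch <- stimulus_epoch(protocol, params)
  rates_at <- function(t) {
    if (!is.null(epoch) && t >= epoch[1] && t < epoch[2]) params$stimulus
    else params$baseline
  }
  with_seed(seed, {
    jumps <- simulate_ctmc(total, boundaries = epoch, rates_at = rates_at,
                           init_state = params$init_state)
    dt <- 1 / protocol$frame_rate
    steps <- n_frames(protocol)
    t <- (0:steps) * dt
    # state at each fencepost; step k is governed by the state at t_k
    idx <- findInterval(t, jumps$times)
    states <- jumps$states[idx]
    heading0 <- params$init_heading %||% stats::runif(1, 0, 2 * pi)
    dtheta <- stats::rnorm(steps, 0, sqrt(params$heading_diffusion * dt))
    heading <- heading0 + cumsum(c(0, dtheta))[-1]  # heading for each step
    st_step <- states[-length(states)]               # state at step start
    mu <- params$speed_mean[st_step]
    sdv <- params$speed_sd[st_step]
    speed <- pmax(0, stats::rnorm(steps, mu, sdv))
    eff <- heading + ifelse(st_step == "reverse", pi, 0)
    dx <- speed * dt * cos(eff)
    dy <- speed * dt * sin(eff)
    if (params$jitter_mm > 0) {
      dx <- dx + stats::rnorm(steps, 0, params$jitter_mm)
      dy <- dy + stats::rnorm(steps, 0, params$jitter_mm)
    }
    x <- cumsum(c(0, dx))
    y <- cumsum(c(0, dy))
    list(
      trajectory = new_trajectory(animal_id, group, t, x, y, protocol),
      states = factor(st_step, levels = STATES),
      jumps = jumps
    )
  })
}

#' Simulate a cohort of locomotion trajectories
#'
#' Each animal uses an independent child stream derived from
#' `(seed, index)`.
#'
#' @inheritParams simulate_trajectory
#' @param n Number of animals.
#' @param id_prefix Prefix for generated animal ids.
#' @return A list with `trajectories`, `states` (list of ground-truth
#'   factors), and `jumps`.
#' @export
simulate_trajectory_cohort <- function(protocol, params, n, seed = 1,
                                       group = "group", id_prefix = group) {
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- simulate_trajectory(
      protocol, params, seed = child_seed(seed, i),
      animal_id = sprintf("%s_%03d", id_prefix, i), group = group
    )
  }
  list(
    trajectories = lapply(out, `[[`, "trajectory"),
    states = lapply(out, `[[`, "states"),
    jumps = lapply(out, `[[`, "jumps")
  )
}

#' Simulate a chemotaxis-assay plate count
#'
#' Worms distribute between the stimulus (test) and control regions of an
#' assay plate as a binomial draw.
#'
#' @param p_test Probability a worm ends on the stimulus side, in `[0, 1]`.
#' @param n_worms Worms on the plate.
#' @param seed Optional seed.
#' @param plate_id Identifier.
#' @return A `chemotaxis_counts` list with `n_test`, `n_control`,
#'   `plate_id`.
#' @export
simulate_chemotaxis_assay <- function(p_test, n_worms, seed = NULL,
                                      plate_id = "plate1") {
  check_number(p_test, "p_test", min = 0)
  if (p_test > 1) abort_invalid("`p_test` must be <= 1")
  if (!is.numeric(n_worms) || n_worms < 1 || n_worms != round(n_worms))
    abort_invalid("`n_worms` must be a positive integer")
  with_seed(seed, {
    n_test <- stats::rbinom(1, n_worms, p_test)
    structure(
      list(n_test = n_test, n_control = n_worms - n_test,
           plate_id = plate_id),
      class = "chemotaxis_counts"
    )
  })
}
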