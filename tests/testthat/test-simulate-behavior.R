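no_switch_params <- function(init_state = "forward", speed = 0.1,
                             frame_rate = 1) {
  locomotion_params(matrix(0, 3, 3), frame_rate = frame_rate,
                    speed_mean = c(speed, speed, 0), speed_sd = c(0, 0, 0),
                    heading_diffusion = 0, init_state = init_state,
                    init_heading = 0)
}

test_that("deterministic limit: zero rates give a straight constant-speed track", {
  p <- make_protocol(3, 4, 3, 1)
  s <- simulate_trajectory(p, no_switch_params(), seed = 1)
  expect_equal(length(s$trajectory$t_s), n_frames(p) + 1L)
  expect_equal(s$trajectory$x_mm, 0.1 * (0:10))
  expect_equal(s$trajectory$y_mm, rep(0, 11))
  expect_true(all(s$states == "forward"))
  # total path length 1.0 mm over 10 s at 0.1 mm/s
  expect_equal(sum(sqrt(diff(s$trajectory$x_mm)^2 + diff(s$trajectory$y_mm)^2)), 1)
})

test_that("deterministic limit: a paused animal with jitter disabled does not move", {
  p <- make_protocol(3, 4, 3, 1)
  s <- simulate_trajectory(p, no_switch_params(init_state = "pause"), seed = 1)
  expect_true(all(s$trajectory$x_mm == 0) && all(s$trajectory$y_mm == 0))
  expect_true(all(s$states == "pause"))
})

test_that("state dwell times are exponential with mean 1 / exit rate", {
  # forward exit rate 0.2/s -> mean sojourn 5 s; constant rates over a long
  # recording; dwell times measured from the continuous-time jump record
  rates <- rate_mat <- matrix(0, 3, 3)
  rate_mat[1, 2] <- 0.1; rate_mat[1, 3] <- 0.1     # forward exits at 0.2/s
  rate_mat[2, 1] <- 1; rate_mat[3, 1] <- 1
  params <- locomotion_params(rate_mat, frame_rate = 1,
                              heading_diffusion = 0)
  p <- make_protocol(4000, 4000, 4000, 1)
  dwells <- c()
  for (i in 1:4) {
    s <- simulate_trajectory(p, params, seed = i)
    j <- s$jumps
    durs <- diff(c(j$times, protocol_duration(p)))
    # drop the censored final sojourn
    fwd <- which(j$states == "forward")
    fwd <- fwd[fwd < length(j$times)]
    dwells <- c(dwells, durs[fwd])
  }
  expect_gt(length(dwells), 1500)
  se <- stats::sd(dwells) / sqrt(length(dwells))
  expect_lt(abs(mean(dwells) - 5), 3 * se)
})

test_that("state occupancy converges to the stationary distribution of the rate matrix", {
  Q <- matrix(c(0, 0.2, 0.1,
                0.5, 0, 0.1,
                0.3, 0.1, 0), 3, 3, byrow = TRUE)
  params <- locomotion_params(Q, frame_rate = 2, heading_diffusion = 0)
  # analytic stationary distribution: pi Q_gen = 0
  gen <- Q; diag(gen) <- -rowSums(Q)
  pi_an <- solve(rbind(t(gen)[1:2, ], rep(1, 3)), c(0, 0, 1))
  occ <- c(forward = 0, reverse = 0, pause = 0)
  p <- make_protocol(1000, 1000, 1000, 2)
  for (i in 1:3) {
    s <- simulate_trajectory(p, params, seed = 100 + i)
    occ <- occ + table(s$states)[names(occ)]
  }
  occ <- occ / sum(occ)
  expect_true(all(abs(occ - pi_an) < 0.02))
})

test_that("trajectories are reproducible under a seed", {
  p <- behavior_protocol()
  params <- locomotion_preset("dauer_like")
  a <- simulate_trajectory(p, params, seed = 5)
  b <- simulate_trajectory(p, params, seed = 5)
  expect_identical(a$trajectory$x_mm, b$trajectory$x_mm)
  expect_identical(a$states, b$states)
})

test_that("stimulus epoch switches rates at pulse onset and respects adaptation", {
  p <- behavior_protocol()
  # dauer-like: pause dominates during the pulse
  co <- simulate_trajectory_cohort(p, locomotion_preset("dauer_like"),
                                   n = 25, seed = 3)
  in_pulse <- function(states, tr) {
    tt <- tr$t_s[-length(tr$t_s)]
    mean(states[tt >= 20 & tt < 80] == "pause")
  }
  pre_pause <- mean(mapply(function(st, tr) {
    tt <- tr$t_s[-length(tr$t_s)]
    mean(st[tt < 20] == "pause")
  }, co$states, co$trajectories))
  stim_pause <- mean(mapply(in_pulse, co$states, co$trajectories))
  expect_gt(stim_pause, 0.6)
  expect_lt(pre_pause, 0.3)
  # adult-like adaptation: late pulse window behaves like baseline
  ca <- simulate_trajectory_cohort(p, locomotion_preset("adult_like"),
                                   n = 25, seed = 4)
  late_pause <- mean(mapply(function(st, tr) {
    tt <- tr$t_s[-length(tr$t_s)]
    mean(st[tt >= 50 & tt < 70] == "pause")
  }, ca$states, ca$trajectories))
  expect_lt(late_pause, 0.3)
})

test_that("chemotaxis assay counts are binomial with the requested probability", {
  expect_equal(unlist(simulate_chemotaxis_assay(1, 20, seed = 1)[1:2]),
               c(n_test = 20, n_control = 0))
  expect_equal(unlist(simulate_chemotaxis_assay(0, 20, seed = 1)[1:2]),
               c(n_test = 0, n_control = 20))
  n <- 1e5
  cts <- simulate_chemotaxis_assay(0.5, n, seed = 2)
  ci <- chemotaxis_index(cts)
  se_ci <- 2 * sqrt(0.25 / n)  # var of index = 4 p q / n
  expect_lt(abs(ci), 3 * se_ci)
  expect_identical(simulate_chemotaxis_assay(0.3, 50, seed = 9)$n_test,
                   simulate_chemotaxis_assay(0.3, 50, seed = 9)$n_test)
})

test_that("invalid locomotion parameters are rejected", {
  expect_error(locomotion_params(matrix(-1, 3, 3)), class = "invalid_argument")
  expect_error(locomotion_params(matrix(0, 2, 2)), class = "invalid_argument")
  expect_error(locomotion_params(matrix(0, 3, 3), speed_mean = c(-1, 0, 0)),
               class = "invalid_argument")
  expect_error(simulate_chemotaxis_assay(1.5, 10), class = "invalid_argument")
})
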