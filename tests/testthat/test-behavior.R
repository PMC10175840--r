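test_that("instantaneous speed recovers displacement over time", {
  p <- make_protocol(1, 1, 1, 1)  # 3 steps, 4 fenceposts
  traj <- traj_from_xy(c(0, 3, 3, 3), c(0, 4, 4, 4), p)
  st <- instantaneous_speed(traj, smooth_s = 0)
  expect_equal(st$speed_mm_s, c(5, 0, 0))  # 3-4-5 triangle
  expect_equal(st$t_s, c(1, 2, 3))
  # stationary track
  still <- traj_from_xy(rep(1, 4), rep(2, 4), p)
  expect_equal(instantaneous_speed(still, smooth_s = 0)$speed_mm_s, rep(0, 3))
})

test_that("smoothing leaves a constant-velocity track unchanged", {
  p <- make_protocol(4, 4, 4, 5)
  n <- n_frames(p) + 1
  traj <- traj_from_xy(0.05 * (0:(n - 1)), rep(0, n), p)
  for (sm in c(0, 1, 3)) {
    st <- instantaneous_speed(traj, smooth_s = sm)
    expect_equal(st$speed_mm_s, rep(0.25, n - 1))
  }
})

test_that("segmentation recovers simple forward, reverse, and pause structure", {
  p <- make_protocol(10, 10, 10, 1)
  n <- n_frames(p)  # 30 steps
  # straight constant-speed: single forward interval covering the span
  straight <- traj_from_xy(0.1 * (0:n), rep(0, n + 1), p)
  seg <- segment_states(straight)
  expect_equal(nrow(seg$intervals), 1)
  expect_equal(seg$intervals$state, "forward")
  expect_equal(c(seg$intervals$start_s, seg$intervals$end_s), c(0, 30))
  # out 15 s then retrace: forward then reverse split at the turn
  x <- c(0.1 * (0:15), 0.1 * (14:0))
  seg2 <- segment_states(traj_from_xy(x, rep(0, n + 1), p))
  expect_equal(seg2$intervals$state, c("forward", "reverse"))
  expect_equal(seg2$intervals$end_s[1], 15)
})

test_that("segmentation matches the brute-force oracle on random small tracks", {
  set.seed(99)
  p <- make_protocol(3, 4, 3, 5)  # 50 steps
  n <- n_frames(p)
  for (case in 1:200) {
    # random piecewise motion: runs of straight motion, retracing, stops
    dx <- numeric(n); dy <- numeric(n)
    i <- 1
    ang <- stats::runif(1, 0, 2 * pi)
    while (i <= n) {
      len <- sample(2:10, 1)
      kind <- sample(c("move", "turn", "stop"), 1)
      if (kind == "turn") ang <- ang + stats::runif(1, -pi, pi)
      sp <- if (kind == "stop") 0.001 else stats::runif(1, 0.05, 0.3)
      idx <- i:min(n, i + len - 1)
      dx[idx] <- sp * 0.2 * cos(ang)
      dy[idx] <- sp * 0.2 * sin(ang)
      i <- i + len
    }
    traj <- traj_from_xy(cumsum(c(0, dx)), cumsum(c(0, dy)), p)
    seg <- segment_states(traj)
    oracle <- oracle_segment(traj$x_mm, traj$y_mm, dt = 0.2,
                             pause_thr = 0.02, min_bout_s = 0.6,
                             angle_deg = 120)
    expect_identical(as.character(seg$frame_states), oracle)
  }
})

test_that("state time ratios partition the window exactly", {
  p <- make_protocol(5, 10, 5, 1)
  n <- n_frames(p)
  # 10 s forward, 5 s pause, 5 s reverse
  dx <- c(rep(0.1, 10), rep(0, 5), rep(-0.1, 5))
  traj <- traj_from_xy(cumsum(c(0, dx)), rep(0, n + 1), p)
  seg <- segment_states(traj)
  r <- state_time_ratios(seg, c(0, 20))
  expect_equal(unname(r), c(0.5, 0.25, 0.25))
  expect_identical(sum(r), 1)
  # window inside the pause
  r2 <- state_time_ratios(seg, c(11, 14))
  expect_equal(unname(r2), c(0, 0, 1))
  # random windows: exact partition identity
  set.seed(7)
  for (i in 1:50) {
    w <- sort(stats::runif(2, 0, 20))
    if (diff(w) < 1e-3) next
    expect_identical(sum(state_time_ratios(seg, w)), 1)
  }
  expect_error(state_time_ratios(seg, c(-1, 5)), class = "invalid_argument")
})

test_that("straight-line distance and reverse distance behave geometrically", {
  p <- make_protocol(20, 60, 40, 1)
  n <- n_frames(p)
  # straight at 0.1 mm/s: 6 mm over the 60-s pulse (endpoints included)
  straight <- traj_from_xy(0.1 * (0:n), rep(0, n + 1), p)
  expect_equal(straight_line_distance(straight, c(20, 80 + 0.5)), 6)
  # out-and-back returns to start
  x <- c(0.1 * (0:(n / 2)), 0.1 * ((n / 2 - 1):0))
  back <- traj_from_xy(x, rep(0, n + 1), p)
  expect_equal(straight_line_distance(back, c(0, 120.5)), 0)
  # reverse distance: a single 5-s reverse bout at 0.2 mm/s
  dx <- rep(0.15, n); dx[31:35] <- -0.2
  traj <- traj_from_xy(cumsum(c(0, dx)), rep(0, n + 1), p)
  seg <- segment_states(traj)
  expect_equal(reverse_distance(traj, seg, c(0, 120)), 1.0)
  expect_equal(reverse_distance(straight, segment_states(straight), c(0, 120)), 0)
  # straight-line <= path length, always
  set.seed(3)
  for (i in 1:20) {
    rw <- traj_from_xy(cumsum(c(0, stats::rnorm(n, 0, 0.1))),
                       cumsum(c(0, stats::rnorm(n, 0, 0.1))), p)
    path <- sum(sqrt(diff(rw$x_mm)^2 + diff(rw$y_mm)^2))
    expect_lte(straight_line_distance(rw, c(0, 121)), path)
  }
})

test_that("behavior metrics are invariant to rigid rotation and translation", {
  p <- behavior_protocol()
  s <- simulate_trajectory(p, locomotion_preset("dauer_like"), seed = 17)
  traj <- s$trajectory
  th <- 0.83
  rot <- traj
  rot$x_mm <- cos(th) * traj$x_mm - sin(th) * traj$y_mm + 12
  rot$y_mm <- sin(th) * traj$x_mm + cos(th) * traj$y_mm - 4
  w <- c(20, 80)
  expect_equal(instantaneous_speed(rot)$speed_mm_s,
               instantaneous_speed(traj)$speed_mm_s)
  seg_a <- segment_states(traj); seg_b <- segment_states(rot)
  expect_identical(as.character(seg_a$frame_states),
                   as.character(seg_b$frame_states))
  expect_equal(straight_line_distance(rot, w), straight_line_distance(traj, w))
  expect_equal(reverse_distance(rot, seg_b, w), reverse_distance(traj, seg_a, w))
})

test_that("behavior cohort table summarizes animals and groups", {
  p <- behavior_protocol()
  n <- n_frames(p)
  mk <- function(id) traj_from_xy(0.03 * (0:n), rep(0, n + 1), p,
                                  animal_id = id)
  bt <- behavior_cohort_table(list(mk("a"), mk("b"), mk("c")))
  expect_equal(nrow(bt$per_animal), 3)
  # identical deterministic tracks: zero between-animal variance
  num <- vapply(bt$per_animal[, -(1:3)], stats::sd, numeric(1))
  expect_true(all(num == 0))
  expect_true(all(bt$speed_summary$sem_mm_s == 0))
  expect_error(behavior_cohort_table(list()), class = "invalid_argument")
})

test_that("dauer-like cohorts pause more than adult-like cohorts under CO2", {
  p <- behavior_protocol()
  dl <- simulate_trajectory_cohort(p, locomotion_preset("dauer_like"),
                                   n = 20, seed = 1, group = "dauer_like")
  al <- simulate_trajectory_cohort(p, locomotion_preset("adult_like"),
                                   n = 20, seed = 2, group = "adult_like")
  bt <- behavior_cohort_table(c(dl$trajectories, al$trajectories))
  m <- tapply(bt$per_animal$pause_ratio, bt$per_animal$group, mean)
  expect_gt(m[["dauer_like"]], m[["adult_like"]] + 0.2)
})
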