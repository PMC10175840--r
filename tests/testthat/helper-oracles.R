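# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use naive loops / full enumeration so they share no code
# path with the implementation they check.

imaging_protocol <- function(fps = 2) make_protocol(30, 60, 60, fps)
behavior_protocol <- function(fps = 5) make_protocol(20, 60, 40, fps)

# Build a calcium_trace directly from a ratio vector (donor constant).
trace_from_ratio <- function(r, protocol, animal_id = "a1", group = "g") {
  t <- frame_times(protocol)
  stopifnot(length(r) == length(t))
  structure(
    list(animal_id = animal_id, neuron = "BAG", group = group, t_s = t,
         donor = rep(1, length(t)), acceptor = r, protocol = protocol),
    class = "calcium_trace"
  )
}

# Build a trajectory from coordinate vectors (fencepost convention).
traj_from_xy <- function(x, y, protocol, animal_id = "w1", group = "g") {
  n <- n_frames(protocol) + 1L
  stopifnot(length(x) == n, length(y) == n)
  structure(
    list(animal_id = animal_id, group = group,
         t_s = (0:(n - 1L)) / protocol$frame_rate, x_mm = x, y_mm = y,
         protocol = protocol),
    class = "trajectory"
  )
}

# --- peak oracle: explicit loop over frames ---------------------------------
oracle_peaks <- function(t_s, dr_pct, window) {
  mx <- -Inf; mn <- Inf
  for (i in seq_along(t_s)) {
    if (t_s[i] >= window[1] && t_s[i] < window[2]) {
      if (dr_pct[i] > mx) mx <- dr_pct[i]
      if (dr_pct[i] < mn) mn <- dr_pct[i]
    }
  }
  c(max_pct = mx, min_pct = mn)
}

# --- segmentation oracle: naive framewise classifier + same merge rule ------
oracle_segment <- function(x, y, dt, pause_thr, min_bout_s, angle_deg,
                           alpha = 0.25) {
  m <- length(x) - 1L
  labels <- character(m)
  dir_forward <- TRUE
  ref <- NA
  thr <- angle_deg * pi / 180
  wrap <- function(d) {
    while (d > pi) d <- d - 2 * pi
    while (d <= -pi) d <- d + 2 * pi
    d
  }
  for (i in 1:m) {
    sp <- sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2) / dt
    if (sp < pause_thr) { labels[i] <- "pause"; next }
    h <- atan2(y[i + 1] - y[i], x[i + 1] - x[i])
    if (is.na(ref)) ref <- h
    else if (abs(wrap(h - ref)) > thr) { dir_forward <- !dir_forward; ref <- h }
    else ref <- ref + alpha * wrap(h - ref)
    labels[i] <- if (dir_forward) "forward" else "reverse"
  }
  # naive merge: repeatedly absorb the shortest sub-threshold bout
  repeat {
    runs <- list()
    i <- 1
    while (i <= m) {
      j <- i
      while (j < m && labels[j + 1] == labels[i]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    }
    if (length(runs) <= 1) break
    durs <- vapply(runs, function(r) (r[2] - r[1] + 1) * dt, numeric(1))
    short <- which(durs < min_bout_s - 1e-9)
    if (length(short) == 0) break
    k <- short[which.min(durs[short])]
    nb <- c(if (k > 1) k - 1, if (k < length(runs)) k + 1)
    take <- nb[which.max(durs[nb])]
    r <- runs[[k]]
    labels[r[1]:r[2]] <- labels[runs[[take]][1]]
  }
  labels
}

# --- exact Mann-Whitney oracle: full enumeration of group assignments -------
oracle_mann_whitney_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(a); N <- length(pooled)
  u_of <- function(x, y) sum(outer(x, y, ">"))
  u_obs <- u_of(a, b)
  idx <- utils::combn(N, n1)
  us <- apply(idx, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  m <- n1 * (N - n1)
  p_one <- if (u_obs > m / 2) mean(us >= u_obs) else mean(us <= u_obs)
  min(1, 2 * p_one)
}

# --- Fisher exact oracle: hypergeometric enumeration ------------------------
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
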