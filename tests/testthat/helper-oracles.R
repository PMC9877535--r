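# Independent oracles used across the suite. These deliberately avoid the
# package's closed forms and code paths: crossings are found by root
# bracketing on the continuous speed profile, variances by direct summation,
# Holm by a literal transcription of the step-down rule.

# continuous minimum-jerk speed (mm/s) of a movement of d mm over T ms,
# starting at t0 ms
oracle_mj_speed <- function(t, t0, d, T) {
  tau <- (t - t0) / T
  ifelse(tau < 0 | tau > 1, 0, 1000 * d / T * 30 * tau^2 * (1 - tau)^2)
}

# the two times at which that profile crosses `frac` of its own peak,
# solved numerically
oracle_mj_crossings <- function(t0, d, T, frac = 0.10) {
  peak <- 1875 * d / T
  thr <- frac * peak
  f <- function(t) oracle_mj_speed(t, t0, d, T) - thr
  up <- uniroot(f, c(t0, t0 + T / 2), tol = 1e-10)$root
  down <- uniroot(f, c(t0 + T / 2, t0 + T), tol = 1e-10)$root
  c(up, down)
}

# build a vm_trial by hand from sampled positions (20 ms grid)
make_trial <- function(x, y, go_time = 4000, condition = "S",
                       target_direction = "right", dt = 20) {
  structure(
    list(participant_id = "T01", condition = condition, trial_index = 1L,
         target_direction = target_direction,
         t = seq(0, by = dt, length.out = length(x)),
         x = x, y = y, go_time = go_time, truth = NULL),
    class = "vm_trial"
  )
}

# constant-speed polyline trial: hold at the origin until `go + rt`, move
# straight to `end1` at `speed` mm/s, optionally pause and move to `end2`.
# Sharp speed steps make arc-length identities exact at sample resolution.
make_polyline_trial <- function(end1, end2 = NULL, speed = 150, rt = 500,
                                pause_ms = 200, go_time = 4000, dt = 20,
                                condition = "S", target_direction = "right") {
  step <- speed * dt / 1000  # mm per sample
  seg <- function(from, to) {
    d <- sqrt(sum((to - from)^2))
    n <- ceiling(d / step)
    list(x = from[1] + (to[1] - from[1]) * seq_len(n) / n,
         y = from[2] + (to[2] - from[2]) * seq_len(n) / n)
  }
  n_hold <- round((go_time + rt) / dt)
  x <- rep(0, n_hold); y <- rep(0, n_hold)
  s1 <- seg(c(0, 0), end1)
  x <- c(x, s1$x); y <- c(y, s1$y)
  if (!is.null(end2)) {
    n_p <- round(pause_ms / dt)
    x <- c(x, rep(end1[1], n_p)); y <- c(y, rep(end1[2], n_p))
    s2 <- seg(end1, end2)
    x <- c(x, s2$x); y <- c(y, s2$y)
  }
  n_tail <- round(600 / dt)
  x <- c(x, rep(x[length(x)], n_tail)); y <- c(y, rep(y[length(y)], n_tail))
  make_trial(x, y, go_time, condition, target_direction, dt)
}

# Cronbach's alpha by brute force: variances as explicit sums of squares
oracle_alpha <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  v <- function(x) sum((x - sum(x) / n)^2) / (n - 1)
  tot <- rowSums(m)
  (k / (k - 1)) * (1 - sum(apply(m, 2, v)) / v(tot))
}

# Holm by literal transcription of the step-down rule
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min(1, (m - i + 1) * p[o[i]]))
    adj[o[i]] <- running
  }
  adj
}

# noiseless kinematics for oracle-driven scoring tests
noiseless_params <- function(...) {
  kinematic_params(endpoint_noise_sd = 0, corrective_prob = 0,
                   reversal_prob = 0,
                   error_probs = c(left_early = 0, rt_out_of_range = 0,
                                   mt_too_long = 0),
                   condition_effects = c(S = 1, PC = 1, FR = 1, `PC+FR` = 1),
                   ...)
}
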