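#' Default per-trial kinematic parameters
#'
#' Parameters of the generative model for one centre-out sliding reach.
#' Trials unfold as: hold at the central target (`hold_ms`), a lognormal
#' reaction period after the go signal, a minimum-jerk primary submovement to
#' the finger-space target with isotropic Gaussian endpoint noise, an optional
#' second (corrective) minimum-jerk submovement, and a terminal hold inside
#' the acquired target. Direction-reversal trials launch the first submovement
#' 135-225 degrees away from the target line before correcting. Error trials
#' are injected by drawing timing parameters outside the task's validity
#' rules (home target left before the 4,000 ms hold elapsed, reaction time
#' below 150 ms or above 8,000 ms, total movement time above 10,000 ms).
#'
#' Times in ms, lengths in mm, sampling at 50 Hz (`dt_ms = 20`).
#' `condition_effects` are multiplicative difficulty factors on movement time
#' and endpoint noise for the non-standard mappings.
#'
#' @param ... named overrides of any default.
#' @return a named list of parameters.
#' @export
kinematic_params <- function(...) {
  p <- list(
    movement_time_mean  = 900,
    movement_time_sd    = 150,
    movement_time_range = c(400, 9000),
    rt_meanlog          = log(450),
    rt_sdlog            = 0.25,
    rt_range            = c(250, 7000),
    endpoint_noise_sd   = 4,
    corrective_prob     = 0.35,
    reversal_prob       = 0.04,
    error_probs         = c(left_early = 0.02, rt_out_of_range = 0.02,
                            mt_too_long = 0.01),
    hold_ms             = 4000,
    acquire_hold_ms     = 500,
    undershoot_mm       = 15,
    corrective_pause_ms = 120,
    corrective_noise_sd = 1.2,
    reversal_dist_mm    = 35,
    reversal_time_ms    = 400,
    dt_ms               = 20,
    condition_effects   = c(S = 1, PC = 1.15, FR = 1.25, `PC+FR` = 1.35)
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown kinematic parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  stopifnot(p$movement_time_mean > 0, p$dt_ms > 0,
            all(p$error_probs >= 0), sum(p$error_probs) <= 1,
            p$corrective_prob >= 0, p$corrective_prob <= 1,
            p$reversal_prob >= 0, p$reversal_prob <= 1)
  p
}

# piecewise minimum-jerk path: list of segments, each
# list(t0, T, from = c(x,y), to = c(x,y)); positions held constant between
# and after segments. Evaluated exactly at arbitrary times.
.piecewise_pos <- function(segments, t) {
  n <- length(t)
  x <- rep(segments[[1]]$from[1], n)
  y <- rep(segments[[1]]$from[2], n)
  for (seg in segments) {
    tau <- (t - seg$t0) / seg$T
    during <- tau >= 0 & tau <= 1
    after  <- tau > 1
    if (any(during)) {
      s <- mj_pos(tau[during])
      x[during] <- seg$from[1] + s * (seg$to[1] - seg$from[1])
      y[during] <- seg$from[2] + s * (seg$to[2] - seg$from[2])
    }
    if (any(after)) {
      x[after] <- seg$to[1]
      y[after] <- seg$to[2]
    }
  }
  cbind(x = x, y = y)
}

.seg_dist <- function(seg) sqrt(sum((seg$to - seg$from)^2))

# analytic segmentation ground truth for a piecewise minimum-jerk trial:
# the scorer's threshold is 10% of the peak speed of the FIRST submovement;
# onset/ballistic offset are that segment's threshold crossings, the total
# offset is the final segment's downward crossing of the same threshold.
.analytic_truth <- function(segments) {
  d1 <- .seg_dist(segments[[1]])
  T1 <- segments[[1]]$T
  pv <- mj_peak_speed(d1, T1)
  thr <- 0.10 * pv
  cr1 <- mj_speed_crossings(thr, d1, T1)
  onset <- segments[[1]]$t0 + cr1[1] * T1
  b_off <- segments[[1]]$t0 + cr1[2] * T1
  if (length(segments) == 1L) {
    return(list(pv = pv, onset = onset, ballistic_offset = b_off,
                total_offset = b_off, cpl = 0))
  }
  last <- segments[[length(segments)]]
  dl <- .seg_dist(last)
  crl <- mj_speed_crossings(thr, dl, last$T)
  if (is.na(crl[2])) {
    # final submovement never reaches the threshold: the scorer will not see
    # it, so the ballistic offset doubles as the total offset
    return(list(pv = pv, onset = onset, ballistic_offset = b_off,
                total_offset = b_off, cpl = 0))
  }
  total <- last$t0 + crl[2] * last$T
  # path travelled between the ballistic and total offsets
  cpl <- d1 * (1 - mj_pos(cr1[2]))
  if (length(segments) > 2L) {
    for (k in seq(2, length(segments) - 1L)) cpl <- cpl + .seg_dist(segments[[k]])
  }
  cpl <- cpl + dl * mj_pos(crl[2])
  list(pv = pv, onset = onset, ballistic_offset = b_off,
       total_offset = total, cpl = cpl)
}

.corrective_duration <- function(d_mm) 300 + 3.5 * d_mm

.clamp_norm <- function(v, max_norm) {
  n <- sqrt(sum(v^2))
  if (n > max_norm) v * (max_norm / n) else v
}

#' Simulate one reaching trial
#'
#' Draws one trial from the generative model described in
#' [kinematic_params()], using the current RNG state. The returned trial
#' carries analytic ground truth: true onset / ballistic-offset /
#' total-offset times (the 10%-of-peak-velocity crossings of the continuous
#' speed profile), the ballistic endpoint, the peak speed, the corrective
#' path length the scorer should measure, and the injected error/reversal
#' flags.
#'
#' @param layout a [target_layout()].
#' @param target_direction `"up"`, `"down"`, `"left"` or `"right"`.
#' @param params list from [kinematic_params()].
#' @param participant_id,trial_index identifiers carried into the output.
#' @return an object of class `vm_trial`: vectors `t`, `x`, `y` (ms, mm, 50
#'   Hz), `go_time`, metadata, and a `truth` list.
#' @export
simulate_trial <- function(layout, target_direction, params = kinematic_params(),
                           participant_id = "P01", trial_index = 1L) {
  stopifnot(inherits(layout, "vm_layout"),
            target_direction %in% vm_directions())
  p <- params
  if (p$movement_time_mean <= 0) stop("movement time must be positive")
  center <- layout$center
  target <- layout$finger_targets[target_direction, ]
  radius <- layout$diameter / 2
  amp <- sqrt(sum((target - center)^2))
  u_dir <- (target - center) / amp

  # -- error / reversal / corrective draws ------------------------------
  u <- stats::runif(1)
  cum <- cumsum(p$error_probs)
  error_kind <- "none"
  if (u < cum[1]) error_kind <- "left_early"
  else if (u < cum[2]) error_kind <- "rt_out_of_range"
  else if (u < cum[3]) error_kind <- "mt_too_long"
  reversal <- error_kind == "none" && stats::runif(1) < p$reversal_prob
  corrective <- error_kind == "none" && !reversal &&
    stats::runif(1) < p$corrective_prob

  # -- spatial plan of the primary submovement --------------------------
  noise1 <- stats::rnorm(2, 0, p$endpoint_noise_sd)
  if (reversal) {
    ang_t <- atan2(u_dir[2], u_dir[1])
    ang_w <- ang_t + pi + stats::runif(1, -pi / 4, pi / 4)
    end1 <- center + p$reversal_dist_mm * c(cos(ang_w), sin(ang_w))
  } else {
    end1 <- target + noise1
    if (corrective) end1 <- target - p$undershoot_mm * u_dir + noise1
    if (error_kind == "mt_too_long") {
      # the stall must happen clearly outside the target disc so that a
      # corrective submovement (and hence a >10 s movement) always follows
      end1 <- target - 2 * radius * u_dir + .clamp_norm(noise1, 0.4 * radius)
    }
  }
  d1 <- sqrt(sum((end1 - center)^2))

  # -- timing -----------------------------------------------------------
  # the scorer measures RT and MT between 10%-of-peak-velocity crossings,
  # which sit at fixed fractions tau1/tau2 of a minimum-jerk submovement:
  # measured RT = drawn RT + tau1 * MT, measured MT ~ (tau2 - tau1) * MT.
  # Error trials are injected on the measured scale so the injected label
  # is what the validity rules will see.
  tau1 <- mj_speed_crossings(0.1 * mj_peak_speed(1, 1), 1, 1)[1]
  tau2 <- 1 - tau1
  rt <- stats::rlnorm(1, p$rt_meanlog, p$rt_sdlog)
  rt <- min(max(rt, p$rt_range[1]), p$rt_range[2])
  mt <- stats::rnorm(1, p$movement_time_mean, p$movement_time_sd)
  mt <- min(max(mt, p$movement_time_range[1]), p$movement_time_range[2])
  if (reversal) mt <- p$reversal_time_ms
  go <- p$hold_ms
  if (error_kind == "rt_out_of_range") {
    measured <- if (stats::runif(1) < 0.7) stats::runif(1, 50, 120)
    else stats::runif(1, 8300, 8800)
    rt <- measured - tau1 * mt
  }
  pause <- p$corrective_pause_ms
  if (error_kind == "mt_too_long") {
    # a reach that stalls short of the target for >10 s before correcting:
    # keeps the peak speed in the normal range while the measured movement
    # time (onset to total offset) exceeds the rule
    pause <- stats::runif(1, 10300, 11500)
  }
  start <- go + rt
  if (error_kind == "left_early") {
    # place the start so the finger exits the central target disc well
    # before the hold period has elapsed, whatever the movement time
    tau_exit <- stats::uniroot(function(u) mj_pos(u) - radius / d1,
                               c(0, 0.5))$root
    start <- go - tau_exit * mt - stats::runif(1, 300, 700)
    rt <- start - go
  }

  segments <- list()
  segments[[1]] <- list(t0 = start, T = mt, from = center, to = end1)
  miss <- sqrt(sum((end1 - target)^2)) > 0.95 * radius
  if (reversal || corrective || miss) {
    noise2 <- .clamp_norm(stats::rnorm(2, 0, p$corrective_noise_sd),
                          0.6 * radius)
    end2 <- target + noise2
    d2 <- sqrt(sum((end2 - segments[[1]]$to)^2))
    t0c <- segments[[1]]$t0 + segments[[1]]$T + pause
    segments[[2]] <- list(t0 = t0c, T = .corrective_duration(d2),
                          from = segments[[1]]$to, to = end2)
  }

  last <- segments[[length(segments)]]
  t_end <- last$t0 + last$T + p$acquire_hold_ms
  t <- seq(0, ceiling(t_end / p$dt_ms) * p$dt_ms, by = p$dt_ms)
  pos <- .piecewise_pos(segments, t)

  truth <- .analytic_truth(segments)
  truth$endpoint <- segments[[1]]$to
  truth$error_kind <- error_kind
  truth$reversal <- reversal
  truth$corrective_arc <- if (length(segments) > 1L)
    .seg_dist(segments[[2]]) else 0
  truth$rt <- truth$onset - go             # measured-scale reaction time
  truth$mt <- truth$total_offset - truth$onset

  structure(
    list(participant_id = participant_id, condition = layout$condition,
         trial_index = as.integer(trial_index),
         target_direction = target_direction,
         t = t, x = pos[, "x"], y = pos[, "y"],
         go_time = go, truth = truth),
    class = "vm_trial"
  )
}

#' @export
print.vm_trial <- function(x, ...) {
  cat("<vm_trial>", x$participant_id, x$condition, x$target_direction,
      "| ", length(x$t), "samples |",
      if (x$truth$error_kind != "none") paste("error:", x$truth$error_kind)
      else if (x$truth$reversal) "direction reversal" else "ok", "\n")
  invisible(x)
}

#' Simulate all trials of one participant
#'
#' For each condition, target order is a seeded pseudo-random permutation of
#' `reps` repetitions of the four directions (the blocked pseudo-random
#' presentation of the task). Condition difficulty multipliers from
#' `params$condition_effects` scale movement time and endpoint noise.
#'
#' @param layouts list from [make_layouts()].
#' @param params [kinematic_params()].
#' @param reps repetitions per target and condition (5 gives the standard 20
#'   trials per condition, 80 per participant).
#' @param participant_id identifier.
#' @return list of `vm_trial`.
#' @export
simulate_participant <- function(layouts = make_layouts(),
                                 params = kinematic_params(),
                                 reps = 5L, participant_id = "P01") {
  trials <- list()
  idx <- 0L
  for (cond in names(layouts)) {
    eff <- params$condition_effects[[cond]]
    if (is.null(eff) || is.na(eff)) eff <- 1
    pc <- params
    pc$movement_time_mean <- params$movement_time_mean * eff
    pc$endpoint_noise_sd  <- params$endpoint_noise_sd * eff
    order <- sample(rep(vm_directions(), reps))
    for (dir in order) {
      idx <- idx + 1L
      trials[[idx]] <- simulate_trial(layouts[[cond]], dir, pc,
                                      participant_id = participant_id,
                                      trial_index = idx)
    }
  }
  trials
}

#' Convert trials to the long tabular format
#'
#' One row per sample: `participant_id, condition, trial_index,
#' target_direction, t_ms, x_mm, y_mm, go_time_ms`, plus ground-truth columns
#' (constant within trial) when `include_truth`.
#'
#' @param trials list of `vm_trial`.
#' @param include_truth attach the generator's ground-truth columns.
#' @return data.frame.
#' @export
trials_to_df <- function(trials, include_truth = TRUE) {
  rows <- lapply(trials, function(tr) {
    n <- length(tr$t)
    d <- data.frame(
      participant_id = rep(tr$participant_id, n),
      condition = rep(tr$condition, n),
      trial_index = rep(tr$trial_index, n),
      target_direction = rep(tr$target_direction, n),
      t_ms = tr$t, x_mm = tr$x, y_mm = tr$y,
      go_time_ms = rep(tr$go_time, n),
      stringsAsFactors = FALSE
    )
    if (include_truth) {
      tt <- tr$truth
      d$gt_onset_ms <- tt$onset
      d$gt_ballistic_offset_ms <- tt$ballistic_offset
      d$gt_total_offset_ms <- tt$total_offset
      d$gt_end_x <- tt$endpoint[1]
      d$gt_end_y <- tt$endpoint[2]
      d$gt_pv <- tt$pv
      d$gt_cpl <- tt$cpl
      d$gt_error_kind <- tt$error_kind
      d$gt_reversal <- tt$reversal
    }
    d
  })
  do.call(rbind, rows)
}

#' Split a long trial table back into per-trial records
#' @param df data.frame as produced by [trials_to_df()].
#' @return list of `vm_trial` (ground truth attached when present).
#' @export
df_to_trials <- function(df) {
  need <- c("participant_id", "condition", "trial_index", "target_direction",
            "t_ms", "x_mm", "y_mm", "go_time_ms")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trial table is missing column(s): ",
                         paste(miss, collapse = ", "))
  key <- interaction(df$participant_id, df$condition, df$trial_index,
                     drop = TRUE, lex.order = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$t_ms), ]
    truth <- NULL
    if ("gt_onset_ms" %in% names(d)) {
      truth <- list(onset = d$gt_onset_ms[1],
                    ballistic_offset = d$gt_ballistic_offset_ms[1],
                    total_offset = d$gt_total_offset_ms[1],
                    endpoint = c(d$gt_end_x[1], d$gt_end_y[1]),
                    pv = d$gt_pv[1], cpl = d$gt_cpl[1],
                    error_kind = d$gt_error_kind[1],
                    reversal = as.logical(d$gt_reversal[1]))
    }
    structure(
      list(participant_id = d$participant_id[1], condition = d$condition[1],
           trial_index = d$trial_index[1],
           target_direction = d$target_direction[1],
           t = d$t_ms, x = d$x_mm, y = d$y_mm,
           go_time = d$go_time_ms[1], truth = truth),
      class = "vm_trial"
    )
  })
}

# deterministic per-participant substream: participant i's draws do not
# depend on the cohort size
.substream_seed <- function(seed, i) {
  ((seed %% 1000003) * 1009 + i * 7919) %% 2147483646 + 1
}
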