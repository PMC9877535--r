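#' Trial validity rules
#'
#' Timing criteria separating valid from error trials: the home target may
#' not be left before the 4,000 ms hold elapses, reaction time must lie in
#' [150, 8,000] ms, and total movement time may not exceed 10,000 ms.
#' `pv_floor` (mm/s) is the minimum peak speed for a supra-threshold speed
#' excursion to count as a movement burst (guards against sensor jitter).
#'
#' @param ... named overrides.
#' @export
trial_rules <- function(...) {
  r <- list(hold_ms = 4000, rt_min = 150, rt_max = 8000, mt_max = 10000,
            pv_floor = 10)
  ov <- list(...)
  bad <- setdiff(names(ov), names(r))
  if (length(bad)) stop("unknown rule(s): ", paste(bad, collapse = ", "))
  r[names(ov)] <- ov
  r
}

.arc_length <- function(x, y, i1, i2) {
  if (i2 <= i1) return(0)
  idx <- i1:i2
  sum(sqrt(diff(x[idx])^2 + diff(y[idx])^2))
}

# first sample at which the finger is outside the central target disc
.center_exit_index <- function(trial, layout) {
  r <- layout$diameter / 2
  d <- sqrt((trial$x - layout$center[1])^2 + (trial$y - layout$center[2])^2)
  out <- which(d > r)
  if (length(out)) out[1] else NA_integer_
}

#' Segment a movement at 10% of peak velocity
#'
#' Finds the first post-go movement burst (first contiguous excursion of the
#' speed above `pv_floor` whose peak exceeds the floor), takes its maximum as
#' the peak velocity PV, and scores: onset = last sample before the PV
#' sample with speed below 0.1 PV; ballistic offset = first sample after the
#' PV sample with speed below 0.1 PV; total offset = final downward crossing
#' of the 0.1 PV threshold at which the finger lies inside the correct
#' finger-space target disc. When the ballistic movement itself ends inside
#' the target and nothing follows, that crossing *is* the final one, so
#' ballistic and total offsets coincide. Thresholds are evaluated at sample
#' resolution (no sub-sample interpolation).
#'
#' @param trial filtered `vm_trial`.
#' @param speed from [trajectory_speed()].
#' @param layout the trial's [target_layout()].
#' @param pv_floor minimum burst peak speed, mm/s.
#' @return list with indices and times of onset / ballistic offset / total
#'   offset, `PV` (mm/s), and `error` (`NA`, `"no_movement"` or
#'   `"unacquired_target"`).
#' @export
segment_movement <- function(trial, speed, layout,
                             pv_floor = trial_rules()$pv_floor) {
  n <- length(speed)
  post <- which(trial$t >= trial$go_time)
  if (!length(post)) return(list(error = "no_movement"))
  above <- speed > pv_floor
  above[seq_len(post[1] - 1)] <- FALSE
  if (!any(above)) return(list(error = "no_movement"))
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  burst <- NULL
  for (k in which(runs$values)) {
    if (max(speed[starts[k]:ends[k]]) > pv_floor) { burst <- k; break }
  }
  if (is.null(burst)) return(list(error = "no_movement"))
  b_idx <- starts[burst]:ends[burst]
  pv_i <- b_idx[which.max(speed[b_idx])]
  pv <- speed[pv_i]
  thr <- 0.10 * pv

  below_pre <- which(speed[seq_len(pv_i - 1)] < thr)
  onset_i <- if (length(below_pre)) max(below_pre) else 1L
  below_post <- which(speed < thr & seq_len(n) > pv_i)
  b_off_i <- if (length(below_post)) min(below_post) else n

  # downward threshold crossings, at or after the ballistic offset, with the
  # finger inside the target disc
  tgt <- layout$finger_targets[trial$target_direction, ]
  inside <- sqrt((trial$x - tgt[1])^2 + (trial$y - tgt[2])^2) <=
    layout$diameter / 2
  j <- seq(2, n)
  cross <- j[speed[j] < thr & speed[j - 1] >= thr & j >= b_off_i & inside[j]]
  if (!length(cross)) return(list(error = "unacquired_target",
                                  onset_i = onset_i, pv_i = pv_i, PV = pv,
                                  onset_ms = trial$t[onset_i]))
  total_i <- max(cross)

  list(error = NA_character_, PV = pv,
       onset_i = onset_i, ballistic_offset_i = b_off_i, total_offset_i = total_i,
       onset_ms = trial$t[onset_i],
       ballistic_offset_ms = trial$t[b_off_i],
       total_offset_ms = trial$t[total_i])
}

#' Classify a trial against the timing rules
#'
#' Rules apply in order: `left_early` if the finger exits the central target
#' before the hold period has elapsed; `rt_out_of_range` if reaction time is
#' below 150 ms or above 8,000 ms; `mt_too_long` if total movement time
#' exceeds 10,000 ms; otherwise `none`. The first matching rule wins.
#'
#' @param trial (filtered) `vm_trial`.
#' @param seg result of [segment_movement()].
#' @param layout the trial's layout.
#' @param rules [trial_rules()].
#' @return character: one of `left_early`, `rt_out_of_range`, `mt_too_long`,
#'   `none`.
#' @export
classify_trial <- function(trial, seg, layout, rules = trial_rules()) {
  exit_i <- .center_exit_index(trial, layout)
  if (!is.na(exit_i) && trial$t[exit_i] < rules$hold_ms) return("left_early")
  if (!is.null(seg$onset_ms)) {
    rt <- seg$onset_ms - trial$go_time
    if (rt < rules$rt_min || rt > rules$rt_max) return("rt_out_of_range")
  }
  if (!is.null(seg$total_offset_ms) && !is.null(seg$onset_ms)) {
    if (seg$total_offset_ms - seg$onset_ms > rules$mt_max)
      return("mt_too_long")
  }
  "none"
}

#' Direction-reversal test
#'
#' A trial is a direction reversal when the finger's heading at the moment
#' it exits the central target boundary deviates strictly more than 90
#' degrees from the straight line to the (finger-space) target, i.e. when
#' the dot product of the exit vector with the centre-to-target vector is
#' negative. At exactly 90 degrees the trial is not a reversal.
#'
#' @param trial (filtered) `vm_trial`.
#' @param layout the trial's layout.
#' @return logical.
#' @export
detect_direction_reversal <- function(trial, layout) {
  exit_i <- .center_exit_index(trial, layout)
  if (is.na(exit_i)) stop("trajectory never exits the central target")
  v_exit <- c(trial$x[exit_i], trial$y[exit_i]) - layout$center
  v_tgt <- layout$finger_targets[trial$target_direction, ] - layout$center
  sum(v_exit * v_tgt) < 0
}

.scored_na_row <- function(trial, error_kind) {
  data.frame(
    participant_id = trial$participant_id, condition = trial$condition,
    trial_index = trial$trial_index,
    target_direction = trial$target_direction,
    onset_ms = NA_real_, ballistic_offset_ms = NA_real_,
    total_offset_ms = NA_real_, RT = NA_real_, MTf = NA_real_,
    PV = NA_real_, PLb = NA_real_, PLf = NA_real_, CPL = NA_real_,
    end_x = NA_real_, end_y = NA_real_,
    error_kind = error_kind, direction_reversal = FALSE, valid = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Score one trial
#'
#' Full per-trial preprocessing: dual-pass filtering, speed computation,
#' 10%-of-peak-velocity segmentation, timing classification,
#' direction-reversal coding and the kinematic measures. Error trials return
#' their flag with all measures `NA`; direction reversals are scored but
#' flagged (they are excluded from aggregation and counted separately).
#'
#' Measures: `RT` = onset - go (ms); `MTf` = total offset - onset (ms);
#' `PV` (mm/s); `PLb`/`PLf` = arc length of the filtered path from onset to
#' the ballistic / total offset (mm); `CPL = PLf - PLb` (mm);
#' `end_x`, `end_y` = ballistic endpoint (mm).
#'
#' @param trial a `vm_trial`.
#' @param layout the trial's [target_layout()].
#' @param filter a [filter_spec()] or `NULL` to skip filtering.
#' @param rules [trial_rules()].
#' @return one-row data.frame (a `ScoredTrial` record).
#' @export
score_trial <- function(trial, layout, filter = filter_spec(),
                        rules = trial_rules()) {
  stopifnot(inherits(layout, "vm_layout"))
  f <- filter_trajectory(trial, filter)
  spd <- trajectory_speed(f)
  seg <- segment_movement(f, spd, layout, pv_floor = rules$pv_floor)
  ek <- classify_trial(f, seg, layout, rules)
  if (ek != "none") return(.scored_na_row(trial, ek))
  if (!is.na(seg$error)) return(.scored_na_row(trial, seg$error))
  rev <- detect_direction_reversal(f, layout)
  plb <- .arc_length(f$x, f$y, seg$onset_i, seg$ballistic_offset_i)
  plf <- plb + .arc_length(f$x, f$y, seg$ballistic_offset_i, seg$total_offset_i)
  data.frame(
    participant_id = trial$participant_id, condition = trial$condition,
    trial_index = trial$trial_index,
    target_direction = trial$target_direction,
    onset_ms = seg$onset_ms, ballistic_offset_ms = seg$ballistic_offset_ms,
    total_offset_ms = seg$total_offset_ms,
    RT = seg$onset_ms - trial$go_time,
    MTf = seg$total_offset_ms - seg$onset_ms,
    PV = seg$PV, PLb = plb, PLf = plf, CPL = plf - plb,
    end_x = f$x[seg$ballistic_offset_i], end_y = f$y[seg$ballistic_offset_i],
    error_kind = "none", direction_reversal = rev, valid = TRUE,
    stringsAsFactors = FALSE
  )
}

#' Score a set of trials
#'
#' @param trials either a list of `vm_trial` or a long trial data.frame
#'   (see [trials_to_df()]).
#' @param layouts named list from [make_layouts()]; each trial is scored
#'   against its condition's layout.
#' @inheritParams score_trial
#' @return data.frame, one row per trial.
#' @export
score_trials <- function(trials, layouts = make_layouts(),
                         filter = filter_spec(), rules = trial_rules()) {
  if (is.data.frame(trials)) trials <- df_to_trials(trials)
  rows <- lapply(trials, function(tr) {
    lay <- layouts[[tr$condition]]
    if (is.null(lay)) stop("no layout for condition '", tr$condition, "'")
    score_trial(tr, lay, filter, rules)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant_id, out$condition, out$trial_index), ]
}
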