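.outlier_measures <- c("RT", "MTf", "PV", "PLf", "CPL")

#' Flag per-trial outliers (2-SD rule)
#'
#' Within each participant x condition cell, a valid non-reversal trial is
#' flagged as an outlier when ANY of RT, MTf, PV, PLf, CPL deviates from the
#' cell mean by more than `k_sd` standard deviations. A single pass is used:
#' means and SDs come from the pre-removal data. Cells with fewer than 3
#' usable trials are left untouched, as is any measure with zero SD.
#'
#' @param scored data.frame from [score_trials()].
#' @param k_sd threshold in SD units (2 is the task's standard rule).
#' @return `scored` with a logical `outlier` column added.
#' @export
flag_outliers <- function(scored, k_sd = 2) {
  stopifnot(k_sd > 0)
  scored$outlier <- FALSE
  key <- interaction(scored$participant_id, scored$condition, drop = TRUE)
  for (cell in levels(key)) {
    idx <- which(key == cell & scored$valid & !scored$direction_reversal)
    if (length(idx) < 3) next
    flag <- rep(FALSE, length(idx))
    for (m in .outlier_measures) {
      v <- scored[[m]][idx]
      mu <- mean(v); s <- stats::sd(v)
      if (!is.finite(s) || s == 0) next
      flag <- flag | abs(v - mu) > k_sd * s
    }
    scored$outlier[idx] <- flag
  }
  scored
}

#' Endpoint accuracy and precision from ballistic endpoints
#'
#' Per target: the centroid of the included ballistic endpoints is computed;
#' absolute error (AE) is the distance from that centroid to the target
#' location, and variable error (VE) the root-mean-square distance of the
#' endpoints about their centroid. Condition-level AE and VE are unweighted
#' means over the four targets; targets with no usable endpoint are dropped
#' with a warning.
#'
#' @param endpoints data.frame with `target_direction`, `end_x`, `end_y`.
#' @param layout the condition's [target_layout()].
#' @param ve `"rms"` (default) or `"mean"` distance about the centroid.
#' @return list `AE`, `VE` (mm; `NA` when no endpoints at all).
#' @export
endpoint_errors <- function(endpoints, layout, ve = c("rms", "mean")) {
  ve <- match.arg(ve)
  ae_t <- c(); ve_t <- c()
  for (dir in vm_directions()) {
    e <- endpoints[endpoints$target_direction == dir, , drop = FALSE]
    if (!nrow(e)) {
      warning("no usable endpoints for target '", dir, "' in condition ",
              layout$condition, "; dropped from AE/VE", call. = FALSE)
      next
    }
    tgt <- layout$finger_targets[dir, ]
    cx <- mean(e$end_x); cy <- mean(e$end_y)
    ae_t <- c(ae_t, sqrt((cx - tgt[1])^2 + (cy - tgt[2])^2))
    d <- sqrt((e$end_x - cx)^2 + (e$end_y - cy)^2)
    ve_t <- c(ve_t, if (ve == "rms") sqrt(mean(d^2)) else mean(d))
  }
  if (!length(ae_t)) return(list(AE = NA_real_, VE = NA_real_))
  list(AE = mean(ae_t), VE = mean(ve_t))
}

#' Aggregate scored trials into per-participant, per-condition outcomes
#'
#' Timing/path measures (RT, MTf, PV, PLf, CPL) are means over valid,
#' non-reversal, non-outlier trials; AE and VE come from the same trials'
#' ballistic endpoints via [endpoint_errors()]; the direction-reversal rate
#' DR_pct is 100 x reversals / completed (non-error) trials. Cells with no
#' usable trial yield `NA` outcomes with a warning.
#'
#' @param scored data.frame from [score_trials()], outlier-flagged (an
#'   `outlier` column is added via [flag_outliers()] if absent).
#' @param layouts [make_layouts()].
#' @param k_sd outlier threshold, used only if flagging is still needed.
#' @param ve VE flavour, see [endpoint_errors()].
#' @return data.frame: participant_id, condition, RT, MTf, PV, PLf, CPL,
#'   AE, VE, DR_pct, n_valid, n_error, n_reversal, n_outlier, n_used.
#' @export
participant_outcomes <- function(scored, layouts = make_layouts(),
                                 k_sd = 2, ve = "rms") {
  if (!"outlier" %in% names(scored)) scored <- flag_outliers(scored, k_sd)
  key <- unique(scored[, c("participant_id", "condition")])
  rows <- vector("list", nrow(key))
  for (r in seq_len(nrow(key))) {
    s <- scored[scored$participant_id == key$participant_id[r] &
                  scored$condition == key$condition[r], , drop = FALSE]
    completed <- s[s$valid, , drop = FALSE]
    used <- completed[!completed$direction_reversal & !completed$outlier, ,
                      drop = FALSE]
    n_rev <- sum(completed$direction_reversal)
    dr <- if (nrow(completed)) 100 * n_rev / nrow(completed) else NA_real_
    if (!nrow(used)) {
      warning("no usable trials for ", key$participant_id[r], " / ",
              key$condition[r], call. = FALSE)
      means <- rep(NA_real_, 5)
      ev <- list(AE = NA_real_, VE = NA_real_)
    } else {
      means <- vapply(c("RT", "MTf", "PV", "PLf", "CPL"),
                      function(m) mean(used[[m]]), numeric(1))
      ev <- endpoint_errors(used, layouts[[key$condition[r]]], ve = ve)
    }
    rows[[r]] <- data.frame(
      participant_id = key$participant_id[r], condition = key$condition[r],
      RT = means[1], MTf = means[2], PV = means[3], PLf = means[4],
      CPL = means[5], AE = ev$AE, VE = ev$VE, DR_pct = dr,
      n_valid = nrow(completed), n_error = sum(!s$valid),
      n_reversal = n_rev,
      n_outlier = sum(completed$outlier & !completed$direction_reversal),
      n_used = nrow(used), stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out[order(out$participant_id, out$condition), ]
}

.zscore <- function(v) {
  s <- stats::sd(v, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(NA_real_, length(v)))
  (v - mean(v, na.rm = TRUE)) / s
}

#' Composite timing and endpoint-error scores
#'
#' Each outcome measure is z-scored across participants within condition;
#' the timing score is the simple average of z(RT), z(MTf) and, by default,
#' -z(PV) (slower peaks mean worse performance, so the sign flip makes
#' higher composite = worse on all items); the endpoint-error score averages
#' z(AE) and z(VE). Measures with zero cohort variance are dropped from the
#' composite with a warning.
#'
#' @param outcomes data.frame from [participant_outcomes()].
#' @param flip_pv reverse PV's sign in the timing composite.
#' @return data.frame: participant_id, condition, timing_score,
#'   endpoint_error_score.
#' @export
composite_scores <- function(outcomes, flip_pv = TRUE) {
  rows <- lapply(split(outcomes, outcomes$condition), function(d) {
    if (sum(stats::complete.cases(d[, c("RT", "MTf", "PV", "AE", "VE")])) < 2)
      warning("fewer than 2 complete participants in condition ",
              d$condition[1], call. = FALSE)
    zt <- cbind(.zscore(d$RT), .zscore(d$MTf),
                if (flip_pv) -.zscore(d$PV) else .zscore(d$PV))
    ze <- cbind(.zscore(d$AE), .zscore(d$VE))
    if (all(is.na(zt[, 3]))) warning("PV has zero cohort variance in ",
                                     d$condition[1], call. = FALSE)
    data.frame(participant_id = d$participant_id, condition = d$condition,
               timing_score = rowMeans(zt, na.rm = TRUE),
               endpoint_error_score = rowMeans(ze, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant_id, out$condition), ]
}

#' Cronbach's alpha
#'
#' Internal consistency of a composite:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(item sums))`,
#' with `n - 1` sample variances over complete cases.
#'
#' @param items numeric matrix or data.frame, participants x items.
#' @return scalar alpha.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  items <- items[stats::complete.cases(items), , drop = FALSE]
  k <- ncol(items)
  if (k < 2) stop("need at least 2 items")
  if (nrow(items) < 3) stop("need at least 3 complete cases")
  tot <- stats::var(rowSums(items))
  if (tot == 0) stop("zero total-score variance; alpha undefined")
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / tot)
}

#' Alpha of the two behavioral composites
#'
#' Computes Cronbach's alpha for the timing composite (items z(RT), z(MTf),
#' -z(PV), z-scored within condition) and the endpoint-error composite
#' (z(AE), z(VE)), over participant x condition rows.
#'
#' @inheritParams composite_scores
#' @return named numeric: `timing`, `endpoint_error`.
#' @export
composite_alphas <- function(outcomes, flip_pv = TRUE) {
  z <- lapply(split(outcomes, outcomes$condition), function(d) {
    data.frame(zRT = .zscore(d$RT), zMTf = .zscore(d$MTf),
               zPV = if (flip_pv) -.zscore(d$PV) else .zscore(d$PV),
               zAE = .zscore(d$AE), zVE = .zscore(d$VE))
  })
  z <- do.call(rbind, z)
  c(timing = cronbach_alpha(z[, c("zRT", "zMTf", "zPV")]),
    endpoint_error = cronbach_alpha(z[, c("zAE", "zVE")]))
}
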