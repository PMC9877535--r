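#' Low-pass filter specification
#'
#' Dual-pass (forward-backward, zero net phase) Butterworth low-pass filter
#' applied independently to the x and y position traces. Defaults match the
#' standard kinematic preprocessing: 4th order, 10 Hz cutoff, 50 Hz sampling.
#'
#' @param order filter order (positive, even).
#' @param cutoff_hz cutoff frequency; must be below Nyquist.
#' @param sampling_hz sampling rate.
#' @param dual_pass filter forward then backward.
#' @export
filter_spec <- function(order = 4L, cutoff_hz = 10, sampling_hz = 50,
                        dual_pass = TRUE) {
  stopifnot(order > 0, order %% 2 == 0, cutoff_hz > 0, sampling_hz > 0)
  if (cutoff_hz >= sampling_hz / 2)
    stop("cutoff (", cutoff_hz, " Hz) must be below the Nyquist frequency (",
         sampling_hz / 2, " Hz)")
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 sampling_hz = sampling_hz, dual_pass = dual_pass),
            class = "vm_filter_spec")
}

# forward-backward Butterworth with odd-reflection edge padding. The pad
# must cover the IIR startup transient (the filter starts from a zero
# state), so it is much longer than the filter order; 100 samples (2 s at
# 50 Hz) leaves the transient below 1e-9 of signal scale at the data edge.
.filtfilt_padded <- function(x, bf) {
  n <- length(x)
  ord <- length(bf$a) - 1L
  pad <- min(max(3L * ord, 100L), n - 1L)
  if (pad > 0) {
    head_pad <- 2 * x[1] - x[seq(pad + 1, 2)]
    tail_pad <- 2 * x[n] - x[seq(n - 1, n - pad)]
    xx <- c(head_pad, x, tail_pad)
  } else xx <- x
  y <- signal::filter(bf, xx)
  y <- rev(signal::filter(bf, rev(y)))
  y <- as.numeric(y)
  if (pad > 0) y <- y[(pad + 1):(pad + n)]
  y
}

#' Filter a trial's position traces
#'
#' @param trial a `vm_trial` (see [simulate_trial()], [df_to_trials()]).
#' @param spec a [filter_spec()]; `NULL` returns the trial unchanged
#'   (useful for hand-constructed test trajectories).
#' @return the trial with `x`, `y` replaced by their filtered versions;
#'   `t` untouched.
#' @export
filter_trajectory <- function(trial, spec = filter_spec()) {
  if (is.null(spec)) return(trial)
  stopifnot(inherits(spec, "vm_filter_spec"))
  dt <- diff(trial$t)
  if (length(dt) < 2) stop("trajectory too short to filter")
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("non-uniform sampling detected; resample to a fixed rate first")
  fs <- 1000 / dt[1]
  if (abs(fs - spec$sampling_hz) > 1e-6 * fs)
    warning("trajectory sampled at ", fs, " Hz but filter spec says ",
            spec$sampling_hz, " Hz; using the trajectory's rate")
  if (spec$cutoff_hz >= fs / 2) stop("cutoff at or above Nyquist")
  bf <- signal::butter(spec$order, spec$cutoff_hz / (fs / 2), type = "low")
  trial$x <- if (spec$dual_pass) .filtfilt_padded(trial$x, bf) else
    as.numeric(signal::filter(bf, trial$x))
  trial$y <- if (spec$dual_pass) .filtfilt_padded(trial$y, bf) else
    as.numeric(signal::filter(bf, trial$y))
  trial
}

#' Tangential speed of a trajectory, mm/s
#'
#' Central differences of the (filtered) x, y traces: a five-point
#' (fourth-order) stencil at interior samples, three-point at the two
#' samples adjacent to the edges, one-sided differences at the ends. The
#' higher-order stencil keeps the speed bias near slow movement onsets an
#' order of magnitude below the 20 ms sampling grid, so threshold-crossing
#' landmarks stay on the correct sample.
#'
#' @param trial a `vm_trial`.
#' @return numeric vector, one speed per sample.
#' @export
trajectory_speed <- function(trial) {
  n <- length(trial$t)
  if (n < 2) stop("need at least 2 samples to compute speed")
  h <- trial$t[2] - trial$t[1]
  deriv <- function(p) {
    v <- numeric(n)
    v[1] <- (p[2] - p[1]) / h
    v[n] <- (p[n] - p[n - 1]) / h
    if (n > 2) {
      v[2] <- (p[3] - p[1]) / (2 * h)
      v[n - 1] <- (p[n] - p[n - 2]) / (2 * h)
    }
    if (n > 4) {
      i <- 3:(n - 2)
      v[i] <- (p[i - 2] - 8 * p[i - 1] + 8 * p[i + 1] - p[i + 2]) / (12 * h)
    }
    v
  }
  vx <- deriv(trial$x)
  vy <- deriv(trial$y)
  1000 * sqrt(vx^2 + vy^2)  # mm/ms -> mm/s
}
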