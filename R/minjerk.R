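#' Minimum-jerk kinematics
#'
#' Closed forms for the straight-line minimum-jerk movement used as the
#' primary (ballistic) submovement model: normalised position
#' s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5 and normalised speed
#' s'(tau) = 30 tau^2 (1 - tau)^2 for tau in [0, 1]. A movement of distance
#' `d` (mm) over duration `T` (ms) has peak speed 1.875 d / T mm/ms
#' (= 1875 d / T mm/s) at tau = 1/2.
#'
#' @name minjerk
#' @keywords internal
NULL

mj_pos <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

mj_speed <- function(tau) {
  v <- 30 * tau^2 * (1 - tau)^2
  v[tau < 0 | tau > 1] <- 0
  v
}

#' Peak speed of a minimum-jerk movement, mm/s
#' @param d_mm movement distance (mm)
#' @param T_ms movement duration (ms)
#' @keywords internal
mj_peak_speed <- function(d_mm, T_ms) 1875 * d_mm / T_ms

# Times (fractions of T) at which the segment's speed equals `speed_mm_s`.
# Returns c(NA, NA) when the segment never reaches that speed.
mj_speed_crossings <- function(speed_mm_s, d_mm, T_ms) {
  f <- speed_mm_s / mj_peak_speed(d_mm, T_ms)
  if (!is.finite(f) || f >= 1 || f < 0) return(c(NA_real_, NA_real_))
  # 30 tau^2(1-tau)^2 = f * 30/16  =>  tau(1-tau) = sqrt(f)/4
  r <- sqrt(1 - sqrt(f))
  c((1 - r) / 2, (1 + r) / 2)
}
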