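test_that("segmentation matches numerically solved 10%-peak-velocity crossings", {
  # hand-built continuous minimum-jerk trials, scored against crossings
  # found by root bracketing on the analytic speed profile
  set.seed(21)
  lay <- target_layout("S")
  for (i in 1:25) {
    mt <- runif(1, 500, 2500)
    rt <- runif(1, 300, 1500)
    dir <- sample(vm_directions(), 1)
    tgt <- lay$finger_targets[dir, ]
    t0 <- 4000 + rt
    t <- seq(0, t0 + mt + 600, by = 20)
    tau <- pmin(pmax((t - t0) / mt, 0), 1)
    s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
    tr <- make_trial(tgt[1] * s, tgt[2] * s, target_direction = dir)
    sc <- score_trial(tr, lay)
    cr <- oracle_mj_crossings(t0, 75, mt)
    expect_lt(abs(sc$onset_ms - cr[1]), 20.1)
    expect_lt(abs(sc$ballistic_offset_ms - cr[2]), 20.1)
    expect_equal(sc$total_offset_ms, sc$ballistic_offset_ms)
    expect_lt(abs(sc$PV / (1875 * 75 / mt) - 1), 0.005)
    expect_equal(sc$CPL, 0)
  }
})

test_that("1 mm endpoint noise keeps detected landmarks within 2 samples in >= 99% of trials", {
  set.seed(22)
  lay <- target_layout("S")
  p <- noiseless_params(endpoint_noise_sd = 1)
  hits <- logical(200)
  for (i in seq_along(hits)) {
    tr <- simulate_trial(lay, sample(vm_directions(), 1), p)
    sc <- score_trial(tr, lay)
    hits[i] <- sc$valid &&
      abs(sc$onset_ms - tr$truth$onset) <= 40 + 1e-9 &&
      abs(sc$ballistic_offset_ms - tr$truth$ballistic_offset) <= 40 + 1e-9 &&
      abs(sc$total_offset_ms - tr$truth$total_offset) <= 40 + 1e-9
  }
  expect_gte(mean(hits), 0.99)
})

test_that("timing classification applies the rules in order", {
  lay <- target_layout("S")
  seg <- list(onset_ms = 4100, total_offset_ms = 4900)  # RT 100, MT 800
  hold <- make_trial(rep(0, 300), rep(0, 300))
  expect_equal(classify_trial(hold, seg, lay), "rt_out_of_range")
  seg <- list(onset_ms = 4500, total_offset_ms = 16500)  # RT 500, MT 12000
  expect_equal(classify_trial(hold, seg, lay), "mt_too_long")
  seg <- list(onset_ms = 4500, total_offset_ms = 5300)   # RT 500, MT 800
  expect_equal(classify_trial(hold, seg, lay), "none")
  # home target left during the hold: overrides any RT violation
  tr <- make_polyline_trial(c(75, 0), rt = -800)
  expect_equal(classify_trial(tr, list(onset_ms = 3200,
                                       total_offset_ms = 3900), lay),
               "left_early")
})

test_that("direction reversal uses a strict 90-degree criterion on the exit heading", {
  lay <- target_layout("S")  # target 'right' at (75, 0)
  heading_trial <- function(angle_deg) {
    a <- angle_deg * pi / 180
    make_polyline_trial(30 * c(cos(a), sin(a)), target_direction = "right")
  }
  expect_false(detect_direction_reversal(heading_trial(0), lay))
  expect_true(detect_direction_reversal(heading_trial(180), lay))
  expect_false(detect_direction_reversal(heading_trial(89.9), lay))
  expect_true(detect_direction_reversal(heading_trial(90.1), lay))
  never_exits <- make_trial(rep(0, 100), rep(0, 100))
  expect_error(detect_direction_reversal(never_exits, lay), "never exits")
})

test_that("corrective path length equals the extra polyline length exactly", {
  lay <- target_layout("S")
  # constant-speed path: 67 mm toward the target, pause, 8 mm correction in
  # (no filtering, so threshold crossings are sharp and arc lengths exact)
  tr <- make_polyline_trial(c(67, 0), end2 = c(75, 0))
  sc <- score_trial(tr, lay, filter = NULL)
  expect_equal(sc$CPL, 8, tolerance = 1e-9)
  expect_equal(sc$PLb, 67, tolerance = 1e-9)
  expect_equal(sc$PLf, 75, tolerance = 1e-9)
  expect_gt(sc$total_offset_ms, sc$ballistic_offset_ms)
  # single straight reach: full and ballistic path coincide
  tr0 <- make_polyline_trial(c(75, 0))
  sc0 <- score_trial(tr0, lay, filter = NULL)
  expect_equal(sc0$PLb, 75, tolerance = 1e-9)
  expect_equal(sc0$CPL, 0)
})

test_that("generated corrective trials carry CPL equal to the analytic ground truth", {
  set.seed(23)
  lay <- target_layout("S")
  p <- noiseless_params(corrective_prob = 1, corrective_noise_sd = 0)
  for (i in 1:10) {
    tr <- simulate_trial(lay, sample(vm_directions(), 1), p)
    sc <- score_trial(tr, lay)
    expect_gt(sc$CPL, 0)
    expect_lt(abs(sc$CPL - tr$truth$cpl), 1.5)
  }
})

test_that("error trials return flags only, and path length dominates displacement", {
  set.seed(24)
  lay <- target_layout("S")
  p <- noiseless_params(error_probs = c(left_early = 1, rt_out_of_range = 0,
                                        mt_too_long = 0))
  sc <- score_trial(simulate_trial(lay, "up", p), lay)
  expect_false(sc$valid)
  expect_equal(sc$error_kind, "left_early")
  expect_true(all(is.na(sc[, c("RT", "MTf", "PV", "PLb", "PLf", "CPL")])))

  # PLf >= straight-line distance between onset and total-offset positions
  pn <- kinematic_params(error_probs = c(left_early = 0, rt_out_of_range = 0,
                                         mt_too_long = 0), reversal_prob = 0)
  for (i in 1:15) {
    tr <- simulate_trial(lay, sample(vm_directions(), 1), pn)
    f <- filter_trajectory(tr)
    sc <- score_trial(tr, lay)
    if (!sc$valid) next
    i1 <- which(f$t == sc$onset_ms); i2 <- which(f$t == sc$total_offset_ms)
    disp <- sqrt((f$x[i2] - f$x[i1])^2 + (f$y[i2] - f$y[i1])^2)
    expect_gte(sc$PLf + 1e-9, disp)
    expect_gte(sc$CPL, 0)
  }
})
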