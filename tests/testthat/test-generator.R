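test_that("peripheral targets sit at the commanded amplitude in every condition", {
  for (cond in vm_conditions()) {
    for (amp in c(75, 1)) {
      lay <- target_layout(cond, amplitude_mm = amp, diameter_mm = amp / 3.75)
      d <- sqrt(rowSums((lay$peripherals -
                           matrix(lay$center, 4, 2, byrow = TRUE))^2))
      expect_equal(unname(d), rep(amp, 4))
      df <- sqrt(rowSums((lay$finger_targets -
                            matrix(lay$center, 4, 2, byrow = TRUE))^2))
      expect_equal(unname(df), rep(amp, 4))
    }
  }
})

test_that("feedback reversal mirrors finger-space targets through the centre", {
  for (cond in c("FR", "PC+FR")) {
    lay <- target_layout(cond)
    expect_equal(lay$finger_targets["up", ], lay$peripherals["down", ])
    expect_equal(lay$finger_targets["left", ], lay$peripherals["right", ])
  }
  for (cond in c("S", "PC")) {
    lay <- target_layout(cond)
    expect_equal(lay$finger_targets, lay$peripherals)
  }
  expect_error(target_layout("XY"), "XY")
})

test_that("trial design yields 80 trials per participant, 20 per condition", {
  set.seed(1)
  trials <- simulate_participant(reps = 5L)
  expect_length(trials, 80)
  conds <- vapply(trials, function(t) t$condition, "")
  expect_equal(as.integer(table(conds)[vm_conditions()]), rep(20L, 4))
  dirs <- vapply(trials, function(t) t$target_direction, "")
  expect_true(all(table(dirs, conds) == 5L))
  set.seed(1)
  expect_length(simulate_participant(reps = 1L), 16)
})

test_that("generated minimum-jerk peak speed matches the closed form 1.875 A/T", {
  set.seed(4)
  p <- noiseless_params(movement_time_mean = 600, movement_time_sd = 0)
  lay <- target_layout("S")
  tr <- simulate_trial(lay, "up", p)
  expect_equal(tr$truth$pv, 234.375, tolerance = 1e-12)
  s <- score_trial(tr, lay)
  expect_lt(abs(s$PV / 234.375 - 1), 0.005)
})

test_that("equal seeds give byte-identical cohorts; substreams survive resizing", {
  spec <- cohort_spec(n_participants = 5, reps = 1, seed = 7)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a, b)
  small <- simulate_cohort(cohort_spec(n_participants = 4, reps = 1, seed = 7))
  expect_identical(small$brain, a$brain[1:4, ])
  expect_identical(small$truth$latent, a$truth$latent[1:4])
})

test_that("the latent composite encodes the moderation exactly at zero noise", {
  be <- default_brain_effect()
  be$noise_sd <- 0
  sim <- simulate_cohort(cohort_spec(n_participants = 40, brain_effect = be,
                                     seed = 3), trials = FALSE)
  d <- data.frame(y = sim$truth$latent, x = sim$brain[[be$x_var]],
                  z = as.numeric(sim$brain$e4))
  fit <- lm(y ~ x * z, data = d)
  expect_equal(unname(coef(fit)),
               unname(be$beta[c("b0", "b1", "b2", "b3")]), tolerance = 1e-9)
})

test_that("injected reversals exit the central target more than 90 degrees off", {
  set.seed(11)
  lay <- target_layout("PC")
  p <- noiseless_params(reversal_prob = 1)
  for (i in 1:10) {
    tr <- simulate_trial(lay, sample(vm_directions(), 1), p)
    expect_true(tr$truth$reversal)
    expect_true(detect_direction_reversal(filter_trajectory(tr), lay))
  }
})

test_that("injected timing errors land in the scored classes they promise", {
  set.seed(12)
  lay <- target_layout("S")
  p_rt <- noiseless_params(error_probs = c(left_early = 0,
                                           rt_out_of_range = 1,
                                           mt_too_long = 0))
  tr <- simulate_trial(lay, "right", p_rt)
  expect_equal(tr$truth$error_kind, "rt_out_of_range")
  expect_equal(score_trial(tr, lay)$error_kind, "rt_out_of_range")
  p_le <- noiseless_params(error_probs = c(left_early = 1,
                                           rt_out_of_range = 0,
                                           mt_too_long = 0))
  tr <- simulate_trial(lay, "up", p_le)
  expect_equal(score_trial(tr, lay)$error_kind, "left_early")
})

test_that("degenerate cohort sizes and parameters are rejected", {
  expect_error(cohort_spec(n_participants = 3), "4")
  expect_error(kinematic_params(movement_time_mean = -5), "movement_time_mean")
  expect_error(kinematic_params(bogus = 1), "bogus")
})
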