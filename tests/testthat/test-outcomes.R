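# minimal scored-trial rows for aggregation tests
scored_row <- function(pid = "P1", cond = "S", idx = 1, dir = "right",
                       RT = 500, MTf = 900, PV = 150, PLf = 80, CPL = 2,
                       end = c(75, 0), error_kind = "none", reversal = FALSE) {
  data.frame(participant_id = pid, condition = cond, trial_index = idx,
             target_direction = dir, onset_ms = 4000 + RT,
             ballistic_offset_ms = 4000 + RT + MTf, total_offset_ms = 4000 +
               RT + MTf, RT = RT, MTf = MTf, PV = PV, PLb = PLf - CPL,
             PLf = PLf, CPL = CPL, end_x = end[1], end_y = end[2],
             error_kind = error_kind, direction_reversal = reversal,
             valid = error_kind == "none", stringsAsFactors = FALSE)
}

test_that("the 2-SD screen flags exactly the trials a brute-force screen flags", {
  rts <- c(rep(500, 9), 5000)
  sc <- do.call(rbind, lapply(seq_along(rts), function(i)
    scored_row(idx = i, RT = rts[i])))
  fl <- flag_outliers(sc)
  # brute force on the one varying measure
  expect_identical(fl$outlier, abs(rts - mean(rts)) > 2 * sd(rts))
  expect_identical(which(fl$outlier), 10L)

  # identical trials: zero SD, nothing flagged
  same <- do.call(rbind, lapply(1:10, function(i) scored_row(idx = i)))
  expect_false(any(flag_outliers(same)$outlier))
  # an infinite threshold flags nothing
  expect_false(any(flag_outliers(sc, k_sd = Inf)$outlier))
  # fewer than 3 usable trials: no screening
  expect_false(any(flag_outliers(sc[1:2, ])$outlier))
})

test_that("absolute and variable error follow the centroid geometry", {
  lay <- target_layout("S")
  on_target <- data.frame(target_direction = rep(vm_directions(), each = 3),
                          end_x = rep(lay$finger_targets[, 1], each = 3),
                          end_y = rep(lay$finger_targets[, 2], each = 3))
  ev <- endpoint_errors(on_target, lay)
  expect_equal(ev$AE, 0)
  expect_equal(ev$VE, 0)

  # symmetric +/- 3 mm pair around each target: centroid on target, RMS 3
  pair <- data.frame(target_direction = rep(vm_directions(), each = 2),
                     end_x = rep(lay$finger_targets[, 1], each = 2) + c(3, -3),
                     end_y = rep(lay$finger_targets[, 2], each = 2))
  ev <- endpoint_errors(pair, lay)
  expect_equal(ev$AE, 0)
  expect_equal(ev$VE, 3)

  # a single endpoint is its own centroid
  single <- data.frame(target_direction = "right",
                       end_x = lay$finger_targets["right", 1] + 5,
                       end_y = lay$finger_targets["right", 2])
  ev <- suppressWarnings(endpoint_errors(single, lay))
  expect_equal(ev$AE, 5)
  expect_equal(ev$VE, 0)
  # mean-distance flavour differs from RMS for asymmetric spreads
  tri <- data.frame(target_direction = "right",
                    end_x = lay$finger_targets["right", 1] + c(-4, 0, 4),
                    end_y = rep(0, 3))
  rms <- suppressWarnings(endpoint_errors(tri, lay, ve = "rms"))$VE
  mn <- suppressWarnings(endpoint_errors(tri, lay, ve = "mean"))$VE
  expect_gt(rms, mn)
})

test_that("reversals count toward DR% and drop out of the means", {
  sc <- do.call(rbind, lapply(1:20, function(i)
    scored_row(idx = i, dir = vm_directions()[(i %% 4) + 1],
               RT = 400 + 10 * i, reversal = i <= 2)))
  sc$outlier <- FALSE
  out <- participant_outcomes(sc)
  expect_equal(out$DR_pct, 10)
  expect_equal(out$n_valid, 20)
  expect_equal(out$n_used, 18)
  expect_equal(out$RT, mean(400 + 10 * (3:20)))

  no_rev <- sc; no_rev$direction_reversal <- FALSE
  expect_equal(participant_outcomes(no_rev)$DR_pct, 0)

  all_err <- sc; all_err$error_kind <- "rt_out_of_range"; all_err$valid <- FALSE
  out <- suppressWarnings(participant_outcomes(all_err))
  expect_true(is.na(out$RT) && is.na(out$AE) && is.na(out$DR_pct))
})

test_that("z-scoring and composites absorb affine rescaling of raw measures", {
  set.seed(31)
  out <- do.call(rbind, lapply(1:12, function(i)
    data.frame(participant_id = sprintf("P%02d", i), condition = "S",
               RT = rnorm(1, 500, 50), MTf = rnorm(1, 900, 90),
               PV = rnorm(1, 150, 20), PLf = 80, CPL = rnorm(1, 5, 2),
               AE = rnorm(1, 6, 2), VE = rnorm(1, 7, 2))))
  comp <- composite_scores(out)
  expect_equal(mean(comp$timing_score), 0, tolerance = 1e-12)
  expect_equal(mean(comp$endpoint_error_score), 0, tolerance = 1e-12)

  rescaled <- out
  rescaled$RT <- 3.2 * out$RT + 40   # e.g. a unit change
  rescaled$AE <- 0.1 * out$AE
  comp2 <- composite_scores(rescaled)
  expect_equal(comp2$timing_score, comp$timing_score, tolerance = 1e-12)
  expect_equal(comp2$endpoint_error_score, comp$endpoint_error_score,
               tolerance = 1e-12)

  # when the two endpoint items agree perfectly the composite is the item
  out$VE <- 2 * out$AE + 1
  comp3 <- composite_scores(out)
  zae <- (out$AE - mean(out$AE)) / sd(out$AE)
  expect_equal(comp3$endpoint_error_score, zae, tolerance = 1e-12)
})

test_that("Cronbach's alpha matches a brute-force variance computation", {
  m <- matrix(c(1, 2, 3, 2, 4, 5, 3, 6, 7, 4, 8, 9), 4, 3, byrow = TRUE)
  expect_equal(cronbach_alpha(m), oracle_alpha(m), tolerance = 1e-12)

  # parallel items (perfectly correlated, equal variance) give alpha = 1
  x <- rnorm(20)
  perf <- cbind(x, x + 1, x - 3)
  expect_equal(cronbach_alpha(perf), 1, tolerance = 1e-9)

  # independent items: alpha near zero at large n
  set.seed(32)
  ind <- cbind(rnorm(10000), rnorm(10000))
  expect_lt(abs(cronbach_alpha(ind)), 0.15)

  expect_error(cronbach_alpha(m[, 1, drop = FALSE]), "2 items")
  expect_error(cronbach_alpha(matrix(1, 5, 3)), "variance")
})
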