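test_that("a noiseless moderated design is recovered to machine precision", {
  set.seed(51)
  d <- data.frame(x = rnorm(30), z = rep(0:1, 15))
  d$y <- 3 + 2 * d$x + 1 * d$z + 0.5 * d$x * d$z
  fit <- suppressWarnings(fit_moderated(d, "y", "x", "z"))  # perfect fit warns
  expect_equal(unname(fit$beta), c(3, 2, 1, 0.5), tolerance = 1e-10)
  expect_equal(fit$r2_adj, 1, tolerance = 1e-10)
  # residuals orthogonal to every design column
  X <- model.matrix(fit$lm)
  expect_lt(max(abs(crossprod(X, residuals(fit$lm)))) /
              max(abs(crossprod(X, d$y))), 1e-9)
})

test_that("degenerate moderators and constant predictors are rejected", {
  d <- data.frame(x = rnorm(20), z = 0)
  d$y <- d$x + rnorm(20)
  expect_error(fit_moderated(d, "y", "x", "z"), "single value")
  d$z <- rep(0:1, 10)
  d$x[d$z == 1] <- 5
  expect_error(fit_moderated(d, "y", "x", "z"), "unidentifiable")
  d$z2 <- d$z * 2
  expect_error(fit_moderated(d, "y", "x", "z2"), "binary")
})

test_that("simple slopes equal per-stratum refits on noiseless data", {
  set.seed(52)
  d <- data.frame(x = rnorm(40), z = rep(0:1, 20))
  d$y <- -1 + 2 * d$x + 0.7 * d$z + 3 * d$x * d$z
  fit <- suppressWarnings(fit_moderated(d, "y", "x", "z"))
  ss <- simple_slopes(fit)
  expect_equal(ss$slope, c(2, 5), tolerance = 1e-10)
  # independent oracle: refit within each stratum
  s0 <- coef(lm(y ~ x, d[d$z == 0, ]))[["x"]]
  s1 <- coef(lm(y ~ x, d[d$z == 1, ]))[["x"]]
  expect_equal(ss$slope, c(s0, s1), tolerance = 1e-10)
  # covariance identity for the z = 1 slope
  v <- fit$cov
  expect_equal(ss$se[2]^2,
               v["x", "x"] + v["x:z", "x:z"] + 2 * v["x", "x:z"],
               tolerance = 1e-12)
})

test_that("Holm adjustment reproduces the hand-computed step-down rule", {
  h <- holm_adjust(c(0.01, 0.04, 0.03))
  expect_equal(h$p_adjusted, c(0.03, 0.06, 0.06))
  expect_identical(h$reject, c(TRUE, FALSE, FALSE))
  expect_equal(holm_adjust(0.2)$p_adjusted, 0.2)
  expect_true(all(holm_adjust(rep(0, 4))$reject))
  expect_error(holm_adjust(c(0.1, 1.4)), "\\[0, 1\\]")

  # random families: match the literal step-down oracle and dominate
  # Bonferroni without ever rejecting less
  set.seed(53)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))^2
    h <- holm_adjust(p)
    expect_equal(h$p_adjusted, oracle_holm(p), tolerance = 1e-12)
    bonf <- pmin(1, length(p) * p) < 0.05
    expect_true(all(h$reject[bonf]))     # Holm rejects whatever Bonferroni does
    expect_true(all(h$p_adjusted <= pmin(1, length(p) * p) + 1e-12))
  }
})

test_that("three-way ANOVA isolates a single shifted factor and matches balanced-case arithmetic", {
  cells <- expand.grid(a = c(0, 1), b = c(0, 1), c = c(0, 1), rep = 1:2)
  d <- data.frame(fh = cells$a == 1, female = cells$b == 1, e4 = cells$c == 1)
  # factor A shifts the mean; B, C and interactions are inert. The +/- 0.5
  # within-cell perturbation is orthogonal to every factor, so it lands in
  # the residual and leaves all factor sums of squares untouched.
  d$y <- 5 + 3 * cells$a + ifelse(cells$rep == 1, 0.5, -0.5)
  tab <- threeway_anova(d, "y")
  a_row <- tab[tab$term == "fh", ]
  others <- tab[!tab$term %in% c("fh", "Residuals"), ]
  expect_equal(a_row$SS, sum((3 * cells$a - mean(3 * cells$a))^2))
  expect_true(all(abs(others$SS) < 1e-12))

  # integer toy data: F for A from the balanced formulas
  set.seed(54)
  d$y <- c(4, 7, 3, 8, 5, 6, 2, 9, 6, 5, 4, 9, 3, 8, 1, 10)
  tab <- threeway_anova(d, "y")
  m <- tapply(d$y, list(d$fh), mean)
  ss_a <- 8 * sum((m - mean(d$y))^2)
  fit_full <- lm(y ~ fh * female * e4, d)
  ms_e <- sum(residuals(fit_full)^2) / 8
  expect_equal(tab$F[tab$term == "fh"], (ss_a / 1) / ms_e, tolerance = 1e-9)

  # balanced designs: Type III totals agree with sequential (Type I) sums
  a1 <- aov(y ~ fh * female * e4, d)
  s1 <- summary(a1)[[1]][["Sum Sq"]]
  expect_equal(sort(tab$SS), sort(s1), tolerance = 1e-9)
})

test_that("ANOVA p-values are uniform under a Gaussian null", {
  set.seed(55)
  p_a <- replicate(400, {
    d <- data.frame(fh = rep(c(TRUE, FALSE), 8),
                    female = rep(c(TRUE, TRUE, FALSE, FALSE), 4),
                    e4 = rep(c(rep(TRUE, 4), rep(FALSE, 4)), 2),
                    y = rnorm(16))
    threeway_anova(d, "y")$p[1]
  })
  expect_gt(ks.test(p_a, "punif")$p.value, 0.01)
})

test_that("moderated-model estimates converge as 1/sqrt(n) on generated cohorts", {
  errs <- vapply(c(50, 200, 800), function(n) {
    sim <- simulate_cohort(cohort_spec(n_participants = n, seed = 56),
                           trials = FALSE)
    d <- data.frame(y = sim$truth$latent, x = sim$brain[[sim$truth$x_var]],
                    z = as.numeric(sim$brain$e4))
    fit <- fit_moderated(d, "y", "x", "z")
    abs(fit$beta[["b3"]] - sim$truth$beta[["b3"]])
  }, numeric(1))
  expect_lt(errs[3], errs[1])  # error shrinks with n
  expect_lt(errs[3] * sqrt(800 / 50), errs[1] * 6)  # roughly root-n scaling
})
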