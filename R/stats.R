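#' Moderated multiple regression
#'
#' Fits the moderation model `Y = b0 + b1*X + b2*Z + b3*X*Z (+ covariates)`
#' by ordinary least squares, where Z is a binary (0/1) moderator. Optional
#' covariates enter additively; with `covariate_interactions = TRUE` their
#' interactions with X are added as well (useful when a control variable is
#' itself allowed to moderate).
#'
#' @param data data.frame with complete or incomplete rows; incomplete rows
#'   on the used variables are dropped.
#' @param y,x,z column names: continuous outcome, continuous predictor,
#'   binary moderator.
#' @param covariates optional character vector of additional columns.
#' @param covariate_interactions also include covariate-by-X interactions.
#' @return object of class `moderated_fit`: `beta` (b0..b3), `se`, `cov`
#'   (full coefficient covariance), `p` per coefficient, `r2`, `r2_adj`,
#'   `F`, `df` (model, residual), `p_overall`, `n`, the underlying `lm` and
#'   the variable names.
#' @examples
#' d <- data.frame(x = rnorm(40), z = rep(0:1, 20))
#' d$y <- 3 + 2 * d$x + d$z + 0.5 * d$x * d$z + rnorm(40, 0, .1)
#' fit_moderated(d, "y", "x", "z")
#' @export
fit_moderated <- function(data, y, x, z, covariates = NULL,
                          covariate_interactions = FALSE) {
  used <- c(y, x, z, covariates)
  miss <- setdiff(used, names(data))
  if (length(miss)) stop("column(s) not in data: ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[, used, drop = FALSE]), used,
            drop = FALSE]
  n <- nrow(d)
  zv <- d[[z]]
  if (is.logical(zv)) zv <- as.numeric(zv)
  if (!all(zv %in% c(0, 1))) stop("moderator '", z, "' must be binary 0/1")
  if (length(unique(zv)) < 2)
    stop("moderator '", z, "' takes a single value; interaction unidentifiable")
  for (lev in c(0, 1)) {
    if (stats::sd(d[[x]][zv == lev]) == 0)
      stop("'", x, "' is constant within ", z, " = ", lev,
           "; interaction unidentifiable")
  }
  d[[z]] <- zv
  rhs <- paste(c(sprintf("%s * %s", .bt(x), .bt(z)),
                 if (!is.null(covariates)) {
                   if (covariate_interactions)
                     c(vapply(covariates, .bt, ""),
                       sprintf("%s:%s", .bt(x), vapply(covariates, .bt, "")))
                   else vapply(covariates, .bt, "")
                 }), collapse = " + ")
  fml <- stats::as.formula(paste(.bt(y), "~", rhs))
  if (n <= length(all.vars(fml)) + 1) stop("too few complete cases (n = ", n, ")")
  fit <- stats::lm(fml, data = d)
  if (fit$rank < length(stats::coef(fit))) stop("rank-deficient design")
  sm <- summary(fit)
  cf <- stats::coef(sm)
  key <- c("(Intercept)", x, z, paste0(x, ":", z))
  if (!all(key %in% rownames(cf))) stop("internal: coefficient names changed")
  beta <- stats::setNames(cf[key, 1], c("b0", "b1", "b2", "b3"))
  se <- stats::setNames(cf[key, 2], c("b0", "b1", "b2", "b3"))
  p <- stats::setNames(cf[key, 4], c("b0", "b1", "b2", "b3"))
  fstat <- sm$fstatistic
  structure(
    list(beta = beta, se = se, cov = stats::vcov(fit), p = p,
         coef_names = key, r2 = sm$r.squared, r2_adj = sm$adj.r.squared,
         F = unname(fstat[1]), df = unname(fstat[2:3]),
         p_overall = stats::pf(fstat[1], fstat[2], fstat[3],
                               lower.tail = FALSE),
         n = n, lm = fit, vars = list(y = y, x = x, z = z,
                                      covariates = covariates)),
    class = "moderated_fit"
  )
}

.bt <- function(v) paste0("`", v, "`")

#' @export
print.moderated_fit <- function(x, digits = 4, ...) {
  cat("Moderated regression:", x$vars$y, "~", x$vars$x, "*", x$vars$z)
  if (length(x$vars$covariates))
    cat(" +", paste(x$vars$covariates, collapse = " + "))
  cat("  (n =", x$n, ")\n")
  tab <- cbind(estimate = x$beta, se = x$se, p = x$p)
  print(round(tab, digits))
  cat(sprintf("R2 = %.4f, adj R2 = %.4f, F(%d, %d) = %.3f, p = %.4g\n",
              x$r2, x$r2_adj, x$df[1], x$df[2], x$F, x$p_overall))
  invisible(x)
}

#' Simple-slopes analysis of a moderated fit
#'
#' The regression of Y on X at each level of the binary moderator:
#' `slope(Z=0) = b1` and `slope(Z=1) = b1 + b3`, with
#' `var(b1 + b3) = var(b1) + var(b3) + 2 cov(b1, b3)`. Each slope gets a
#' two-sided t test on the fit's residual degrees of freedom.
#'
#' @param fit a [fit_moderated()] result.
#' @return data.frame with rows `z0`, `z1`: slope, se, t, p, df.
#' @export
simple_slopes <- function(fit) {
  stopifnot(inherits(fit, "moderated_fit"))
  if (is.null(fit$cov)) stop("fit carries no coefficient covariance")
  nm <- fit$coef_names
  b1 <- fit$beta[["b1"]]; b3 <- fit$beta[["b3"]]
  v1 <- fit$cov[nm[2], nm[2]]
  v3 <- fit$cov[nm[4], nm[4]]
  c13 <- fit$cov[nm[2], nm[4]]
  slope <- c(z0 = b1, z1 = b1 + b3)
  se <- c(z0 = sqrt(v1), z1 = sqrt(v1 + v3 + 2 * c13))
  df <- fit$df[2]
  tv <- slope / se
  data.frame(moderator_level = c(0, 1), slope = unname(slope),
             se = unname(se), t = unname(tv),
             p = 2 * stats::pt(abs(tv), df, lower.tail = FALSE),
             df = df, row.names = c("z0", "z1"))
}

#' Holm step-down familywise correction
#'
#' Adjusts a family of p-values with the Holm procedure (uniformly more
#' powerful than Bonferroni at the same familywise error rate) and reports
#' which hypotheses are rejected at `alpha`.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param alpha familywise significance level.
#' @return data.frame: `p`, `p_adjusted` (original order), `reject`.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))
#' @export
holm_adjust <- function(p, alpha = 0.05) {
  if (!length(p)) stop("empty p-value vector")
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "holm")
  data.frame(p = p, p_adjusted = adj, reject = adj < alpha)
}

#' Three-way between-subjects ANOVA
#'
#' Compares a measure between the two levels of three binary factors (by
#' default family history, sex and APOE e4 carriage) with all interactions,
#' using Type III sums of squares under sum-to-zero contrasts -- the
#' appropriate choice for the unbalanced cells of an observational cohort.
#'
#' @param data data.frame.
#' @param response column name of the measure.
#' @param factors character(3): the grouping columns (coerced to factors).
#' @return data.frame per term: SS, df, F, p (residual row included).
#' @export
threeway_anova <- function(data, response,
                           factors = c("fh", "female", "e4")) {
  stopifnot(length(factors) == 3, all(c(response, factors) %in% names(data)))
  d <- data[stats::complete.cases(data[, c(response, factors)]),
            c(response, factors)]
  for (f in factors) {
    d[[f]] <- factor(d[[f]])
    if (nlevels(d[[f]]) < 2) stop("factor '", f, "' has a single level")
  }
  fml <- stats::as.formula(paste(.bt(response), "~",
                                 paste(vapply(factors, .bt, ""),
                                       collapse = " * ")))
  ctr <- stats::setNames(rep(list("contr.sum"), 3), factors)
  fit <- stats::lm(fml, data = d, contrasts = ctr)
  a3 <- car::Anova(fit, type = 3)
  tab <- as.data.frame(a3)
  tab <- tab[rownames(tab) != "(Intercept)", ]
  data.frame(term = rownames(tab), SS = tab[["Sum Sq"]], df = tab[["Df"]],
             F = tab[["F value"]], p = tab[["Pr(>F)"]],
             row.names = NULL, stringsAsFactors = FALSE)
}
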