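#' Pipeline configuration
#'
#' Bundles every tunable of the simulate -> score -> outcomes -> adjust-icv
#' -> analyze chain: the cohort specification, the filter, the outlier rule,
#' composite options, the model roster and the familywise alpha. The whole
#' run is driven by the cohort spec's master seed.
#'
#' @param cohort a [cohort_spec()].
#' @param filter a [filter_spec()].
#' @param rules [trial_rules()].
#' @param k_sd outlier threshold (SD units).
#' @param flip_pv,ve composite options, see [composite_scores()] and
#'   [endpoint_errors()].
#' @param models model roster data.frame, see [default_model_roster()].
#' @param alpha familywise significance level.
#' @return list of class `vm_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), filter = filter_spec(),
                            rules = trial_rules(), k_sd = 2,
                            flip_pv = TRUE, ve = "rms",
                            models = default_model_roster(), alpha = 0.05) {
  structure(list(cohort = cohort, filter = filter, rules = rules,
                 k_sd = k_sd, flip_pv = flip_pv, ve = ve,
                 models = models, alpha = alpha),
            class = "vm_config")
}

#' Default moderated-model roster
#'
#' One row per fitted model: outcome (`timing_score`,
#' `endpoint_error_score`, or `CPL`), brain predictor column, condition,
#' moderator and covariates. Mirrors the study design: in the
#' feedback-reversal condition models are moderated by sex and control for
#' family history (with its X interaction, so five predictor terms); in the
#' two plane-change conditions they are moderated by APOE e4 status alone
#' (three predictor terms). Holm families group models sharing an outcome,
#' condition and measurement modality.
#'
#' @param predictors brain columns used as X (adjusted volumes are looked up
#'   in the ICV-adjusted table, thickness/diffusion in the raw table).
#' @export
default_model_roster <- function(predictors = c("vol.lh.presubiculum",
                                                "vol.rh.presubiculum",
                                                "vol.rh.subiculum",
                                                "thk.rh.entorhinal",
                                                "vol.lh.parahippocampal",
                                                "dti.ilf.rh.fa")) {
  grid <- rbind(
    expand.grid(condition = "FR", y = "endpoint_error_score",
                moderator = "male", covariates = "fh",
                covariate_interactions = TRUE,
                x = predictors, stringsAsFactors = FALSE),
    expand.grid(condition = c("PC", "PC+FR"),
                y = c("endpoint_error_score", "CPL"),
                moderator = "e4", covariates = "", covariate_interactions = FALSE,
                x = predictors, stringsAsFactors = FALSE)
  )
  modality <- ifelse(grepl("^dti\\.", grid$x), "dti",
                     ifelse(grepl("^thk\\.", grid$x), "thickness", "volume"))
  grid$family <- paste(grid$condition, grid$y, modality, sep = "|")
  grid
}

# ---------------------------------------------------------------- I/O ----

.write_table <- function(df, path, sep) {
  # serialize doubles at full (17 significant digit) precision so that
  # write -> read round-trips reproduce them bit-exactly
  for (cl in names(df)) {
    if (is.double(df[[cl]])) {
      v <- formatC(df[[cl]], digits = 17, format = "g")
      v[is.na(df[[cl]])] <- "NA"
      df[[cl]] <- v
    }
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
}

#' Format adapters for the pipeline's tabular artifacts
#'
#' Trials travel as comma-separated long tables, everything else as
#' tab-separated tables; numbers are serialized at full precision and
#' round-trip losslessly on the schema fields. Reading validates that the
#' required columns are present and numeric columns parse as numbers
#' (locale decimal commas are rejected).
#'
#' @param df data.frame to write.
#' @param path file path.
#' @name pipeline_io
#' @export
write_trials <- function(df, path) .write_table(df, path, ",")

#' @rdname pipeline_io
#' @export
write_tsv <- function(df, path) .write_table(df, path, "\t")

.check_numeric <- function(df, cols, path) {
  for (cl in intersect(cols, names(df))) {
    if (is.character(df[[cl]])) {
      bad <- grep(",", df[[cl]])
      if (length(bad))
        stop("column '", cl, "' in ", path, " line ", bad[1] + 1,
             " contains a comma decimal; use '.' as the decimal separator")
      stop("column '", cl, "' in ", path, " is not numeric")
    }
  }
  df
}

#' @rdname pipeline_io
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "condition", "trial_index", "target_direction",
            "t_ms", "x_mm", "y_mm", "go_time_ms")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trial file ", path, " is missing column(s): ",
                         paste(miss, collapse = ", "))
  .check_numeric(df, c("t_ms", "x_mm", "y_mm", "go_time_ms"), path)
}

#' @rdname pipeline_io
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# ------------------------------------------------------------- stages ----

.analyze_models <- function(roster, composites, brain, adjusted, alpha) {
  wide <- stats::reshape(composites, direction = "wide",
                         idvar = "participant_id", timevar = "condition")
  rows <- list()
  for (k in seq_len(nrow(roster))) {
    m <- roster[k, ]
    ycol <- paste0(m$y, ".", m$condition)
    if (!ycol %in% names(wide)) next
    xcol <- m$x
    xsrc <- if (grepl("^vol\\.", xcol) && xcol %in% names(adjusted))
      adjusted else brain
    d <- data.frame(participant_id = brain$participant_id,
                    x = xsrc[[xcol]][match(brain$participant_id,
                                           xsrc$participant_id)],
                    fh = as.numeric(brain$fh),
                    male = as.numeric(!brain$female),
                    e4 = as.numeric(brain$e4))
    if (m$moderator == "e4") d$e4[!brain$e4_known] <- NA
    d$y <- wide[[ycol]][match(d$participant_id, wide$participant_id)]
    covs <- if (nzchar(m$covariates))
      strsplit(m$covariates, "+", fixed = TRUE)[[1]] else NULL
    fit <- tryCatch(
      fit_moderated(d, "y", "x", m$moderator, covariates = covs,
                    covariate_interactions = isTRUE(m$covariate_interactions)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[k]] <- data.frame(condition = m$condition, y = m$y, x = m$x,
                              moderator = m$moderator, family = m$family,
                              skipped = conditionMessage(fit),
                              n = NA, b1 = NA, b2 = NA, b3 = NA,
                              se_b3 = NA, p_interaction = NA, r2_adj = NA,
                              F = NA, df1 = NA, df2 = NA,
                              slope_z0 = NA, se_z0 = NA, p_z0 = NA,
                              slope_z1 = NA, se_z1 = NA, p_z1 = NA,
                              stringsAsFactors = FALSE)
      next
    }
    ss <- simple_slopes(fit)
    rows[[k]] <- data.frame(condition = m$condition, y = m$y, x = m$x,
                            moderator = m$moderator, family = m$family,
                            skipped = NA_character_, n = fit$n,
                            b1 = fit$beta[["b1"]], b2 = fit$beta[["b2"]],
                            b3 = fit$beta[["b3"]], se_b3 = fit$se[["b3"]],
                            p_interaction = fit$p[["b3"]],
                            r2_adj = fit$r2_adj, F = fit$F,
                            df1 = fit$df[1], df2 = fit$df[2],
                            slope_z0 = ss$slope[1], se_z0 = ss$se[1],
                            p_z0 = ss$p[1],
                            slope_z1 = ss$slope[2], se_z1 = ss$se[2],
                            p_z1 = ss$p[2], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$p_interaction_holm <- NA_real_
  res$reject <- NA
  for (fam in unique(res$family)) {
    idx <- which(res$family == fam & is.na(res$skipped) &
                   is.finite(res$p_interaction))
    if (!length(idx)) next
    h <- holm_adjust(res$p_interaction[idx], alpha)
    res$p_interaction_holm[idx] <- h$p_adjusted
    res$reject[idx] <- h$reject
  }
  res
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order -- `simulate` (cohort trials and
#' brain table), `score` (per-trial kinematics), `outcomes` (aggregation,
#' outlier removal, composites, alphas), `adjust_icv` (control-fit
#' residuals), `analyze` (moderated regressions, simple slopes, Holm) --
#' writing each artifact as a plain-text table under `out_dir`, together
#' with a `run_info.json` recording the seed and per-stage row counts.
#' A fixed seed and config yield byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param stages subset of the stage names above; later stages read the
#'   earlier artifacts from `out_dir`, so provided input files can be
#'   dropped in place of the simulate stage.
#' @return (invisibly) the output directory.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = c("simulate", "score", "outcomes",
                                    "adjust_icv", "analyze")) {
  stopifnot(inherits(config, "vm_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  layouts <- make_layouts(config$cohort$amplitude_mm,
                          config$cohort$diameter_mm)
  info <- list(seed = config$cohort$seed, stages = stages, counts = list())
  p <- function(f) file.path(out_dir, f)

  if ("simulate" %in% stages) {
    sim <- simulate_cohort(config$cohort)
    write_trials(sim$trials, p("trials.csv"))
    write_tsv(sim$brain, p("brain.tsv"))
    info$counts$simulate <- list(participants = nrow(sim$brain),
                                 trials = length(unique(interaction(
                                   sim$trials$participant_id,
                                   sim$trials$condition,
                                   sim$trials$trial_index))))
  }
  if ("score" %in% stages) {
    trials <- read_trials(p("trials.csv"))
    scored <- score_trials(trials, layouts, config$filter, config$rules)
    write_tsv(scored, p("scored.tsv"))
    info$counts$score <- list(trials = nrow(scored),
                              errors = sum(!scored$valid))
  }
  if ("outcomes" %in% stages) {
    scored <- read_tsv(p("scored.tsv"))
    scored <- flag_outliers(scored, config$k_sd)
    outcomes <- participant_outcomes(scored, layouts, config$k_sd, config$ve)
    composites <- composite_scores(outcomes, config$flip_pv)
    alphas <- composite_alphas(outcomes, config$flip_pv)
    write_tsv(outcomes, p("outcomes.tsv"))
    write_tsv(composites, p("composites.tsv"))
    write_tsv(data.frame(composite = names(alphas), alpha = unname(alphas)),
              p("alphas.tsv"))
    info$counts$outcomes <- list(cells = nrow(outcomes))
  }
  if ("adjust_icv" %in% stages) {
    brain <- read_tsv(p("brain.tsv"))
    val <- validate_brain_table(brain)
    adj <- tryCatch(icv_residualize(val$table), error = function(e) {
      warning("ICV adjustment skipped: ", conditionMessage(e), call. = FALSE)
      list(adjusted = data.frame(participant_id = val$table$participant_id),
           fits = data.frame(column = character(), intercept = numeric(),
                             slope = numeric(), n_controls = integer()))
    })
    write_tsv(adj$adjusted, p("brain_adjusted.tsv"))
    write_tsv(adj$fits, p("icv_fits.tsv"))
    info$counts$adjust_icv <- list(participants = nrow(adj$adjusted),
                                   rois = nrow(adj$fits),
                                   rejected = nrow(val$rejected),
                                   dropped_dti = length(val$dropped_columns))
  }
  if ("analyze" %in% stages) {
    brain <- read_tsv(p("brain.tsv"))
    adjusted <- read_tsv(p("brain_adjusted.tsv"))
    outcomes <- read_tsv(p("outcomes.tsv"))
    composites <- read_tsv(p("composites.tsv"))
    composites <- merge(composites,
                        outcomes[, c("participant_id", "condition", "CPL")],
                        by = c("participant_id", "condition"))
    res <- .analyze_models(config$models, composites, brain, adjusted,
                           config$alpha)
    write_tsv(res, p("models.tsv"))
    jsonlite::write_json(res, p("models.json"), dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
    info$counts$analyze <- list(models = nrow(res),
                                skipped = sum(!is.na(res$skipped)))
  }
  jsonlite::write_json(info, p("run_info.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
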