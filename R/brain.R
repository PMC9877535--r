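#' Validate a participant brain-measure table
#'
#' Checks a per-participant table of ROI volumes (`vol.<hemi>.<roi>`, mm^3),
#' cortical thickness (`thk.<hemi>.<roi>`, mm), diffusion metrics
#' (`dti.<tract>.<metric>`, FA unitless in [0, 1]; MD/RD/AxD in 1e-3
#' mm^2/s), `icv` (mm^3) and the group labels `fh`, `female`, `e4`,
#' `e4_known`. Rows violating range invariants are rejected with a recorded
#' reason; diffusion columns missing in more than `max_missing` participants
#' are dropped (the practice used when a tract cannot be tracked reliably).
#' Participants whose genotyping is inconclusive keep `e4_known = FALSE` and
#' are excluded downstream from APOE-moderated analyses only.
#'
#' @param brain data.frame.
#' @param max_missing drop a diffusion column when missing in more than this
#'   many participants (default 5).
#' @return list: `table` (clean rows, surviving columns), `rejected`
#'   (data.frame participant_id / reason), `dropped_columns` (character).
#' @export
validate_brain_table <- function(brain, max_missing = 5) {
  need <- c("participant_id", "icv", "fh", "female", "e4", "e4_known")
  miss <- setdiff(need, names(brain))
  if (length(miss)) stop("brain table is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(brain$participant_id))
    stop("duplicate participant ids in brain table")

  vol_cols <- grep("^vol\\.", names(brain), value = TRUE)
  thk_cols <- grep("^thk\\.", names(brain), value = TRUE)
  dti_cols <- grep("^dti\\.", names(brain), value = TRUE)
  fa_cols <- grep("\\.fa$", dti_cols, value = TRUE)

  reasons <- character(nrow(brain))
  for (i in seq_len(nrow(brain))) {
    r <- brain[i, ]
    if (!is.finite(r$icv) || r$icv <= 0) reasons[i] <- "non-positive ICV"
    else if (length(vol_cols) &&
             any(!is.na(r[vol_cols]) & r[vol_cols] <= 0))
      reasons[i] <- "non-positive volume"
    else if (length(thk_cols) &&
             any(!is.na(r[thk_cols]) & r[thk_cols] <= 0))
      reasons[i] <- "non-positive thickness"
    else if (length(fa_cols) &&
             any(!is.na(r[fa_cols]) & (r[fa_cols] < 0 | r[fa_cols] > 1)))
      reasons[i] <- "FA outside [0,1]"
  }
  rejected <- data.frame(participant_id = brain$participant_id[reasons != ""],
                         reason = reasons[reasons != ""],
                         stringsAsFactors = FALSE)
  clean <- brain[reasons == "", , drop = FALSE]

  dropped <- dti_cols[vapply(dti_cols,
                             function(cl) sum(is.na(clean[[cl]])) > max_missing,
                             logical(1))]
  if (length(dropped)) {
    message("dropping ", length(dropped),
            " diffusion column(s) missing in more than ", max_missing,
            " participants: ", paste(dropped, collapse = ", "))
    clean <- clean[, setdiff(names(clean), dropped), drop = FALSE]
  }
  list(table = clean, rejected = rejected, dropped_columns = dropped)
}

#' ICV adjustment of regional volumes by the control-fit residuals method
#'
#' For each volume column, a simple regression `VOI = a + b * ICV` is fit by
#' least squares on the control participants only (controls: no family
#' history of dementia AND APOE e4 non-carrier with conclusive genotyping);
#' the adjusted value for *every* participant is the residual from that
#' control line. The control fit captures the non-pathological
#' volume-head-size scaling, so suspected atrophy in at-risk participants
#' does not flatten the slope. Thickness columns are never adjusted
#' (thickness does not scale with head size).
#'
#' @param brain validated brain table (see [validate_brain_table()]).
#' @param volume_cols columns to adjust; default all `vol.*` columns.
#' @param control_mask logical; default `!fh & !e4 & e4_known`.
#' @return list: `adjusted` (participant_id + residual columns, same names),
#'   `fits` (per-column intercept, slope, n_controls).
#' @export
icv_residualize <- function(brain,
                            volume_cols = grep("^vol\\.", names(brain),
                                               value = TRUE),
                            control_mask = NULL) {
  if (is.null(control_mask))
    control_mask <- !brain$fh & !brain$e4 & brain$e4_known
  stopifnot(length(control_mask) == nrow(brain))
  adjusted <- data.frame(participant_id = brain$participant_id,
                         stringsAsFactors = FALSE)
  fits <- list()
  for (cl in volume_cols) {
    ok <- control_mask & !is.na(brain[[cl]]) & !is.na(brain$icv)
    if (sum(ok) < 3) stop("fewer than 3 controls with complete ICV and ", cl)
    icv_c <- brain$icv[ok]
    if (stats::sd(icv_c) == 0) {
      warning("ICV constant among controls; skipping ", cl, call. = FALSE)
      next
    }
    fit <- stats::lm(brain[[cl]][ok] ~ icv_c)
    a <- stats::coef(fit)[1]; b <- stats::coef(fit)[2]
    adjusted[[cl]] <- brain[[cl]] - (a + b * brain$icv)
    fits[[cl]] <- data.frame(column = cl, intercept = unname(a),
                             slope = unname(b), n_controls = sum(ok),
                             stringsAsFactors = FALSE)
  }
  list(adjusted = adjusted,
       fits = if (length(fits)) do.call(rbind, c(fits, make.row.names = FALSE))
       else data.frame(column = character(), intercept = numeric(),
                       slope = numeric(), n_controls = integer()))
}
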