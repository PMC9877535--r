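#' Cohort specification
#'
#' Defines a synthetic study cohort: its size, the prevalence of the binary
#' group labels (family history of dementia, sex, APOE e4 carriage), the
#' trial design, the per-trial kinematic model, and the moderated
#' brain-behavior link. The defaults describe a typical aging cohort for
#' this task: 49 participants (25 FH+, 24 female, 16 of 47 genotyped
#' participants e4+), 4 conditions x 4 targets x 5 repetitions = 80 trials,
#' and a latent performance composite generated as
#' `Y = b0 + b1*X + b2*Z + b3*X*Z + e`, `e ~ N(0, noise_sd)`, with X the
#' right entorhinal cortical thickness and Z the APOE e4 carrier indicator.
#' The default betas place the model at the study's operating point
#' (interaction -7.759, carrier simple slope -6.32, model R^2 near 0.39).
#'
#' @param n_participants cohort size (>= 4).
#' @param p_fh,p_female,p_e4,p_e4_known Bernoulli probabilities of the group
#'   labels; `p_e4_known` is the probability that genotyping is conclusive.
#' @param reps repetitions per target within condition.
#' @param kinematic_params see [kinematic_params()].
#' @param brain_effect list: `x_var` (brain column driving behavior), `beta`
#'   (b0, b1, b2, b3), `noise_sd`.
#' @param latent_scaling multipliers translating one unit of the latent
#'   composite into log-scale changes of endpoint noise, movement time and
#'   reaction time.
#' @param amplitude_mm,diameter_mm task geometry.
#' @param dti_missing_prob per-cell missingness of diffusion values.
#' @param seed master seed; participant-level substreams are derived from it
#'   so that cohorts are reproducible under resizing.
#' @return list of class `vm_cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 49,
                        p_fh = 25 / 49, p_female = 24 / 49,
                        p_e4 = 16 / 47, p_e4_known = 47 / 49,
                        reps = 5L,
                        kinematic_params = vmreach::kinematic_params(),
                        brain_effect = default_brain_effect(),
                        latent_scaling = c(endpoint = 0.25, mt = 0.10,
                                           rt = 0.05),
                        amplitude_mm = 75, diameter_mm = 20,
                        dti_missing_prob = 0.02,
                        seed = 1L) {
  stopifnot(n_participants >= 4,
            all(c(p_fh, p_female, p_e4, p_e4_known) >= 0),
            all(c(p_fh, p_female, p_e4, p_e4_known) <= 1),
            reps >= 1, seed == floor(seed))
  structure(
    list(n_participants = as.integer(n_participants),
         p_fh = p_fh, p_female = p_female, p_e4 = p_e4,
         p_e4_known = p_e4_known, reps = as.integer(reps),
         kinematic_params = kinematic_params,
         brain_effect = brain_effect, latent_scaling = latent_scaling,
         amplitude_mm = amplitude_mm, diameter_mm = diameter_mm,
         dti_missing_prob = dti_missing_prob,
         seed = as.integer(seed)),
    class = "vm_cohort_spec"
  )
}

#' Default moderated brain-behavior effect
#'
#' X is the right entorhinal thickness (mm); Z the APOE e4 indicator. The
#' interaction b3 = -7.759 and carrier simple slope b1 + b3 = -6.32 match
#' the study's entorhinal operating point; b2 = -3 * b3 zeroes the group
#' shift at the mean thickness of 3 mm, and b0 centres the latent composite.
#' `noise_sd = 1.15` puts the model R^2 near 0.39.
#'
#' @export
default_brain_effect <- function() {
  b3 <- -7.759
  b1 <- -6.32 - b3
  b2 <- -3 * b3
  b0 <- -b1 * 3
  list(x_var = "thk.rh.entorhinal",
       beta = c(b0 = b0, b1 = b1, b2 = b2, b3 = b3),
       noise_sd = 1.15)
}

# region-of-interest volume means/sds (mm^3), FreeSurfer-scale magnitudes
.vol_rois <- function() {
  data.frame(
    roi = c("presubiculum", "subiculum", "ca1", "ca23", "ca4dg",
            "parahippocampal", "entorhinal", "perirhinal", "retrosplenial",
            "inferiorparietal", "precuneus"),
    mean = c(320, 430, 640, 220, 270, 2100, 1800, 2400, 2600, 12500, 10000),
    stringsAsFactors = FALSE
  )
}

.thk_rois <- function() {
  data.frame(
    roi = c("parahippocampal", "entorhinal", "perirhinal", "retrosplenial",
            "inferiorparietal", "precuneus"),
    mean = c(2.6, 3.0, 2.9, 2.4, 2.4, 2.3),
    sd = c(0.15, 0.25, 0.15, 0.15, 0.15, 0.15),
    stringsAsFactors = FALSE
  )
}

.tracts <- function() c("cgc.lh", "cgc.rh", "fminor", "fmajor",
                        "ifof.lh", "ifof.rh", "ilf.lh", "ilf.rh",
                        "slf.lh", "slf.rh", "uf.lh", "uf.rh")

.dti_metrics <- function() {
  # means/sds in 1e-3 mm^2/s for MD/RD/AxD, unitless for FA
  data.frame(metric = c("fa", "md", "rd", "axd"),
             mean = c(0.45, 0.80, 0.55, 1.25),
             sd = c(0.035, 0.04, 0.04, 0.05),
             stringsAsFactors = FALSE)
}

.icv_mean <- 1.45e6
.icv_sd <- 1.2e5

# one participant's brain-measure row, drawn from the current RNG stream
.simulate_brain_row <- function(dti_missing_prob = 0) {
  icv <- max(stats::rnorm(1, .icv_mean, .icv_sd), 9e5)
  row <- list(icv = icv)
  vr <- .vol_rois()
  for (h in c("lh", "rh")) {
    for (k in seq_len(nrow(vr))) {
      mu <- vr$mean[k]
      # positive ICV loading plus ROI-specific noise
      v <- mu + 0.5 * mu / .icv_mean * (icv - .icv_mean) +
        stats::rnorm(1, 0, 0.09 * mu)
      row[[paste("vol", h, vr$roi[k], sep = ".")]] <- max(v, 0.2 * mu)
    }
  }
  tr <- .thk_rois()
  for (h in c("lh", "rh")) {
    for (k in seq_len(nrow(tr))) {
      row[[paste("thk", h, tr$roi[k], sep = ".")]] <-
        max(stats::rnorm(1, tr$mean[k], tr$sd[k]), 0.5)
    }
  }
  dm <- .dti_metrics()
  for (tract in .tracts()) {
    for (k in seq_len(nrow(dm))) {
      v <- stats::rnorm(1, dm$mean[k], dm$sd[k])
      if (dm$metric[k] == "fa") v <- min(max(v, 0.05), 0.95)
      else v <- max(v, 0.05)
      if (dti_missing_prob > 0 && stats::runif(1) < dti_missing_prob)
        v <- NA_real_
      row[[paste("dti", tract, dm$metric[k], sep = ".")]] <- v
    }
  }
  row
}

#' Simulate a full cohort
#'
#' Draws, per participant: group labels, a brain-measure row (ROI volumes
#' with a positive ICV loading, cortical thickness, tract diffusion metrics),
#' a latent performance composite from the moderated model of the spec, and
#' (optionally) all 80 trials, whose endpoint noise, movement time and
#' reaction time scale monotonically with the latent composite. Every
#' participant is generated from a deterministic substream of the master
#' seed, so the same participants are obtained for any cohort size.
#'
#' @param spec a [cohort_spec()].
#' @param trials generate trial trajectories (set `FALSE` for brain-only
#'   simulations, e.g. large statistical recovery studies).
#' @return list with `trials` (long data.frame or `NULL`), `brain`
#'   (one row per participant: labels, ICV, measures), and `truth`
#'   (generator parameters, per-participant latent composite).
#' @export
simulate_cohort <- function(spec = cohort_spec(), trials = TRUE) {
  stopifnot(inherits(spec, "vm_cohort_spec"))
  if (spec$n_participants < 4)
    stop("need at least 4 participants to form groups")
  layouts <- make_layouts(spec$amplitude_mm, spec$diameter_mm)
  be <- spec$brain_effect
  b <- be$beta
  ids <- sprintf("P%03d", seq_len(spec$n_participants))

  brain_rows <- vector("list", spec$n_participants)
  trial_dfs <- vector("list", spec$n_participants)
  latent <- numeric(spec$n_participants)
  labels <- data.frame(participant_id = ids, fh = NA, female = NA,
                       e4 = NA, e4_known = NA)

  for (i in seq_len(spec$n_participants)) {
    set.seed(.substream_seed(spec$seed, i))
    fh <- stats::runif(1) < spec$p_fh
    female <- stats::runif(1) < spec$p_female
    e4 <- stats::runif(1) < spec$p_e4
    e4_known <- stats::runif(1) < spec$p_e4_known
    row <- .simulate_brain_row(spec$dti_missing_prob)
    x <- row[[be$x_var]]
    if (is.null(x)) stop("brain_effect$x_var '", be$x_var,
                         "' is not a generated brain column")
    z <- as.numeric(e4)
    eps <- if (be$noise_sd > 0) stats::rnorm(1, 0, be$noise_sd) else 0
    lat <- b[["b0"]] + b[["b1"]] * x + b[["b2"]] * z + b[["b3"]] * x * z + eps
    latent[i] <- lat

    labels$fh[i] <- fh; labels$female[i] <- female
    labels$e4[i] <- e4; labels$e4_known[i] <- e4_known
    brain_rows[[i]] <- row

    if (trials) {
      sc <- spec$latent_scaling
      kp <- spec$kinematic_params
      kp$endpoint_noise_sd <- kp$endpoint_noise_sd * exp(sc[["endpoint"]] * lat)
      kp$movement_time_mean <- kp$movement_time_mean * exp(sc[["mt"]] * lat)
      kp$rt_meanlog <- kp$rt_meanlog + sc[["rt"]] * lat
      tl <- simulate_participant(layouts, kp, reps = spec$reps,
                                 participant_id = ids[i])
      trial_dfs[[i]] <- trials_to_df(tl)
    }
  }

  brain <- cbind(labels,
                 do.call(rbind, lapply(brain_rows, function(r)
                   as.data.frame(r, stringsAsFactors = FALSE))))
  rownames(brain) <- NULL
  list(
    trials = if (trials) do.call(rbind, trial_dfs) else NULL,
    brain = brain,
    truth = list(beta = b, noise_sd = be$noise_sd, x_var = be$x_var,
                 latent = latent, labels = labels, seed = spec$seed)
  )
}
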