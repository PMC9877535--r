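---
title: "Scoring decoupled visuomotor reaching and linking it to brain structure"
author: "vmreach"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring decoupled visuomotor reaching and linking it to brain structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The task and what the package computes

`vmreach` implements the full analysis chain for a centre-out sliding
reaching task under four visuomotor mappings: standard (`S`, gaze and hand
coupled), plane-change (`PC`, hand moves on a horizontal surface while the
target is vertical), feedback-reversal (`FR`, the cursor moves opposite to
the finger), and their combination (`PC+FR`). Four peripheral targets sit
75 mm from a central home target (diameter 20 mm); each is reached 5 times
per condition, giving 20 trials per condition and 80 per participant.
Finger position is sampled at 50 Hz.

The chain is:

1. **Simulation** of cohorts of trials and matched brain-measure tables
   with known ground truth (`simulate_cohort()`);
2. **Kinematic scoring** of each trial (`score_trials()`): dual-pass
   Butterworth filtering, 10%-of-peak-velocity segmentation, error
   classification, direction-reversal coding, and the measures RT, MTf,
   PV, PLb, PLf, CPL and the ballistic endpoint;
3. **Outcome aggregation** (`participant_outcomes()`,
   `composite_scores()`): a single-pass 2-SD outlier screen, per-condition
   means, endpoint accuracy (AE) and precision (VE), the direction-reversal
   rate, and two composites built from within-condition z-scores with
   Cronbach's alpha as the consistency check;
4. **ICV adjustment** of regional brain volumes by the control-fit
   residuals method (`icv_residualize()`);
5. **Moderated regression** of behavior on brain structure
   (`fit_moderated()`, `simple_slopes()`, `holm_adjust()`,
   `threeway_anova()`).

Every stage is driven by the scripts under `analysis/` and orchestrated by
`run_pipeline()`; all artifacts are plain text and byte-reproducible under
a fixed seed.

## The generative model of a trial

Real recordings of this task exist only as summary statistics, so the
generator is built from the standard motor-control conventions and the
task's published design, and every assumption is a named, configurable
parameter (`kinematic_params()`):

* **Primary submovement: minimum jerk.** The ballistic reach follows the
  minimum-jerk profile `s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5`, the
  classic smoothness-optimal model for point-to-point reaching. Its peak
  speed has the closed form `1.875 A / T` (234.375 mm/s for a 75 mm reach
  in 600 ms), and its 10%-of-peak crossings sit at fixed fractions
  `tau = 0.0865` and `0.9135` of the movement — this gives the scorer an
  analytic oracle accurate to the sampling grid.
* **Finger space.** Trajectories are generated and scored in the space of
  the finger, where movement actually happens; the feedback reversal is
  encoded in the layout's `finger_targets` (mirrored through the centre).
* **Timing.** Reaction time is lognormal (heavy right tail, median 450 ms);
  movement time is Gaussian (mean 900 ms, SD 150 ms, truncated at 400 ms).
  The non-standard mappings multiply movement time and endpoint noise by
  condition factors (1.15, 1.25, 1.35 for PC, FR, PC+FR) to emulate
  decoupling costs.
* **Endpoint noise and corrections.** Ballistic endpoints get isotropic
  Gaussian noise (SD 4 mm). A corrective submovement — a second, smaller
  minimum-jerk segment after a 120 ms stall — occurs with probability
  0.35 (deliberate 15 mm undershoot) and always when the ballistic
  endpoint misses the target disc, so every completed trial ends inside
  the target and CPL > 0 exactly when a correction exists.
* **Direction reversals** (probability 0.04) launch the first submovement
  135-225 degrees away from the target line before correcting.
* **Error trials** are injected on the *measured* scale. The scorer
  measures RT from the 10%-threshold onset (≈ drawn RT + 0.0865 MT) and MT
  between threshold crossings (≈ 0.827 MT), so naive injection of raw
  parameter values would sometimes produce trials the classifier legally
  scores otherwise. Reaction-time violations are drawn directly in the
  measured window (50-120 ms or 8.3-8.8 s); over-long movements are
  generated as a normal-speed reach that stalls outside the target disc
  for 10.3-11.5 s before correcting (keeping peak speed above the burst
  floor); early home-exits place the movement start so the finger leaves
  the 10 mm home disc 300-700 ms before the 4,000 ms hold elapses.
* **Seeds.** One master seed; each participant is generated from a
  deterministic substream, so participant *i* is identical in any cohort
  size and two runs with the same seed are byte-identical.

### The moderated brain-behavior link

Per participant the generator draws group labels (family history of
dementia, sex, APOE e4 carriage with a 47/49 probability of conclusive
genotyping), an ICV (mean 1.45 L, SD 0.12 L), regional volumes with a
positive ICV loading plus ROI noise, cortical thickness, and tract
diffusion metrics within physiologic ranges. A latent performance
composite is then drawn from the moderation model

    Y = b0 + b1*X + b2*Z + b3*X*Z + e,   e ~ N(0, noise_sd)

with X the right entorhinal cortical thickness (mm) and Z the APOE e4
indicator. The defaults put the model at a realistic operating point for
this literature: interaction `b3 = -7.759`, carrier simple slope
`b1 + b3 = -6.32` (so `b1 = 1.439`), `b2 = -3 b3` (which zeroes the group
shift at the 3 mm mean thickness) and `b0 = -3 b1`. With thickness SD
0.25 and carrier prevalence 16/47, the systematic variance is

    E[Var(Y | Z)] ~ (1 - p) b1^2 sd_x^2 + p (b1 + b3)^2 sd_x^2 ~ 0.92,

so `noise_sd = 1.15` (variance 1.32) yields a model R^2 of about 0.41 —
near the 0.35-0.43 range reported for such models. The latent composite
scales each participant's endpoint noise (`exp(0.25 Y)`), movement time
(`exp(0.10 Y)`) and reaction time (`exp(0.05 Y)`), so worse latent
performance produces slower, sloppier trials and the behavioral composites
recovered downstream correlate with the latent truth.

## Numerical choices in the scorer

* **Filtering.** 4th-order low-pass Butterworth at 10 Hz, applied forward
  and backward (zero net phase). The IIR filter starts from a zero state,
  so each pass is run on an odd-reflection padding of the trace; 100
  samples (2 s) of padding keep the startup transient below 1e-9 of
  signal scale at the data edges. Constant traces pass through unchanged
  and a second filtering changes arc length by under 0.1%.
* **Speed.** Central differences on the filtered path; interior samples
  use the five-point (fourth-order) stencil. A three-point stencil's
  O(h^2) bias is ~5% of the (small, quadratically-rising) speed near slow
  onsets, enough to shift a threshold crossing across a sample boundary;
  the fourth-order stencil keeps that bias orders of magnitude below the
  20 ms grid, so detected landmarks sit on the sample adjacent to the
  true crossing in all 1,000 oracle trials.
* **Segmentation.** The first post-go movement burst is the first
  contiguous excursion of speed above a 10 mm/s floor (a jitter guard);
  PV is its maximum. Onset is the last sample before the PV sample with
  speed below 0.1 PV; the ballistic offset is the first such sample after
  it; the total offset is the *final* downward crossing of 0.1 PV at
  which the finger lies inside the target disc — when nothing follows the
  ballistic movement, that crossing is the ballistic offset itself, so
  both offsets coincide and CPL = 0. Crossings are evaluated at sample
  resolution: no sub-sample interpolation, matching the 20 ms recording
  grid and keeping the oracle exact.
* **Classification order.** left-early (home disc exited before the
  4,000 ms hold), then RT outside [150, 8,000] ms, then MT above
  10,000 ms; the first match wins and error trials carry no measures.
* **Reversal test.** Strictly more than 90 degrees between the centre-exit
  vector and the centre-to-target vector, i.e. a negative dot product;
  exactly 90 degrees is not a reversal.

## Outcome aggregation decisions

Several details are under-determined by the published descriptions; the
package fixes them as follows (each is a visible argument):

* **Outlier screen**: single pass (not iterated), per participant x
  condition, on {RT, MTf, PV, PLf, CPL}, trials beyond 2 SD on *any*
  measure removed; cells with fewer than 3 usable trials and zero-variance
  measures are left alone. AE/VE are aggregate-level and cannot flag
  single trials, but endpoints of flagged trials are excluded from them.
* **AE/VE per target, then averaged**: the centroid formula is only
  meaningful per target; VE is the RMS distance about the centroid (a
  mean-distance flavour is available).
* **Composites**: measures are z-scored within condition across the
  cohort (the regressions compare participants within a condition);
  the timing composite averages z(RT), z(MTf) and -z(PV), the sign flip
  making "higher = worse" on every item — without it PV (where faster
  peaks accompany better performance) would cancel against RT and MTf and
  the composite's internal consistency would collapse. The flip is a flag
  (`flip_pv`). Cronbach's alpha is computed on the participant x condition
  rows of the z-scored item matrix.
* **DR%**: reversals as a percentage of completed (non-error) trials;
  reversal trials are excluded from all other measures.

## ICV adjustment and the statistical layer

Regional volumes are adjusted with the residuals method: the volume-on-ICV
line is fit by least squares on controls only — participants with no
family history of dementia who are conclusively APOE e4-negative — and
residuals from that line are taken for everyone, so suspected atrophy in
at-risk groups cannot flatten the normative slope. Fits are per ROI and
per hemisphere. Thickness is never adjusted (it does not scale with head
size). Control residuals are exactly zero-mean and ICV-orthogonal (OLS
identities, verified to 1e-9 relative).

The moderation model is fit by OLS on `[1, X, Z, XZ, covariates]`. Simple
slopes are `b1` at Z = 0 and `b1 + b3` at Z = 1 with
`var(b1 + b3) = var(b1) + var(b3) + 2 cov(b1, b3)`, each tested two-sided
on the residual df. Families of interaction p-values are Holm-corrected;
one family per outcome x condition x measurement modality, a grouping the
roster (`default_model_roster()`) makes explicit and configurable because
the published analyses do not enumerate their families. In the
feedback-reversal condition the default models are sex-moderated and
control for family history and its X interaction (five predictor terms);
in the two plane-change conditions they are APOE-moderated with the pure
three-predictor model. Participants with inconclusive genotyping are
excluded from APOE-moderated models only. Group comparisons of brain
measures use three-way ANOVAs (family history x sex x APOE) with Type III
sums of squares under sum-to-zero contrasts — the appropriate convention
for unbalanced observational cells; in balanced designs they coincide
with sequential sums, which the tests verify.

## What the tests do and do not show

The suite checks the pipeline against *analytic* ground truth: closed-form
minimum-jerk landmarks, constant-speed polylines with exact arc lengths,
hand-computed Holm adjustments and balanced-ANOVA arithmetic, exact OLS
identities, and Monte-Carlo recovery at the generator's operating point
(95% CI coverage of `b3 = -7.759` at n = 47 over 500 replicates; null
simple-slope type-I error at n = 49 over 2,000 replicates). Problem sizes
were chosen so the whole suite runs in minutes on one core: 1,000 trials
for the segmentation and classification oracles, 200-500 replicates for
recovery studies, cohorts of 8-14 participants for end-to-end determinism.

Passing these tests shows the *implementation* is faithful to its stated
rules; it cannot show the generator matches real aging-cohort kinematics.
Real trajectories contain tremor, sensor dropout, online corrections that
overlap the primary submovement, and non-Gaussian endpoint error, none of
which are modelled; the published per-trial distributions needed to
calibrate them do not exist. Results that depend on those features —
especially the absolute values of Cronbach's alpha and of the
direction-reversal rate — should be read as demonstrations of the
machinery, not as empirical claims about older adults.

## Known limitations

* Scoring assumes one dominant movement burst; overlapping submovements
  merge into a single ballistic segment, as they would under the
  threshold rule applied to real data.
* The published analyses mention manual verification of movement profiles
  by visual inspection; that step is not reproducible and is omitted.
* The generator's moderation acts through a single brain variable at a
  time; real covariance among ROIs is not modelled beyond the common ICV
  loading.
* MRI and DTI image processing (surface reconstruction, subfield
  segmentation, tractography) is out of scope; brain measures enter as
  tabular values.
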