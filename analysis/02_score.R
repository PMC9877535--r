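#!/usr/bin/env Rscript
# Stage 2: kinematic scoring.
#
# Filters every trajectory (4th-order dual-pass Butterworth, 10 Hz), scores
# movement onset / ballistic offset / total offset at 10% of peak velocity,
# classifies error trials (early home exit, RT out of [150, 8000] ms,
# movement time > 10 s), codes direction reversals (> 90 degrees off the
# target line at centre exit) and computes RT, MTf, PV, PLb, PLf, CPL and
# the ballistic endpoint per trial.

suppressPackageStartupMessages(library(vmreach))

out_dir <- "results/pipeline"
cfg <- pipeline_config()
run_pipeline(cfg, out_dir, stages = "score")

scored <- read_tsv(file.path(out_dir, "scored.tsv"))
cat("Scored", nrow(scored), "trials\n")
cat("  error trials:", sum(!scored$valid), "\n")
print(table(scored$error_kind))
cat("  direction reversals:", sum(scored$direction_reversal, na.rm = TRUE),
    "\n")
cat("  median RT:", round(median(scored$RT, na.rm = TRUE)), "ms;",
    "median MTf:", round(median(scored$MTf, na.rm = TRUE)), "ms;",
    "median PV:", round(median(scored$PV, na.rm = TRUE)), "mm/s\n")
cat("artifact:", file.path(out_dir, "scored.tsv"), "\n")
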