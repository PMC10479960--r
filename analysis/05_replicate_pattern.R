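#!/usr/bin/env Rscript
# Stage 5: replication frequency of the significance pattern.
#
# Draws 200 replicate cohorts at the calibrated per-cell index
# distributions (generator level: the calibration SDs already subsume
# measurement noise, since they derive from observed SEMs) and records how
# often each component of the reported significance pattern recurs, plus
# how often the full pattern recurs jointly. Writes
# results/replicate_pattern.csv.

library(ovomemri)

n_rep <- 200
rows <- lapply(seq_len(n_rep), function(r) {
  coh <- sample_cohort(cohort_spec(master_seed = 5000L + r), render = FALSE)
  tab <- cohort_table(data.frame(
    subject_id = coh$truth$subject_id, condition = coh$truth$condition,
    region = coh$truth$region, lateralization_index = coh$truth$li_true))
  rep <- run_full_analysis(tab)
  bt <- rep$between_condition
  os <- rep$one_sample
  data.frame(
    replicate = r,
    dark_thal_mean = mean(tab$lateralization_index[
      tab$region == "thalamus_gld" & tab$condition == "dark"]),
    thal_between_sig = bt$p_fdr[bt$region == "thalamus_gld"] < 0.05,
    dark_thal_sig = os$p[os$region == "thalamus_gld" &
                           os$condition == "dark"] < 0.05,
    light_wulst_sig = os$p[os$region == "wulst" &
                             os$condition == "light"] < 0.05,
    tectum_all_null = bt$p_fdr[bt$region == "optic_tectum"] >= 0.05 &&
      all(os$p[os$region == "optic_tectum"] >= 0.05)
  )
})
res <- do.call(rbind, rows)
res$full_pattern <- res$thal_between_sig & res$dark_thal_sig &
  res$light_wulst_sig & res$tectum_all_null

dir.create("results", showWarnings = FALSE)
write.csv(res, "results/replicate_pattern.csv", row.names = FALSE)

cat(sprintf("Dark-thalamus grand mean: %.4f (MC SE %.4f; calibration %.3f)\n",
            mean(res$dark_thal_mean),
            sd(res$dark_thal_mean) / sqrt(n_rep), -0.038))
cat("Component replication frequencies over", n_rep, "cohorts:\n")
print(round(colMeans(res[, c("thal_between_sig", "dark_thal_sig",
                             "light_wulst_sig", "tectum_all_null",
                             "full_pattern")]), 3))
cat("The near-threshold printed effect sizes cap the power of the\n",
    "thalamus between-condition and light-Wulst tests near 50-60%, so\n",
    "the full joint pattern recurs in well under half of replicates.\n")
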