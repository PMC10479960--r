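#!/usr/bin/env Rscript
# Stage 4: group statistics.
#
# Runs the full battery on the subject records of stage 3: 2(condition) x
# 3(region) mixed ANOVA, per-region between-condition pooled t-tests with
# Benjamini-Hochberg FDR across the three regions, six one-sample tests of
# the index against chance (uncorrected), and Cohen's d throughout. Writes
# the JSON report and flat CSVs under results/pipeline/.

library(ovomemri)

res <- run_pipeline(list(paths = list(input_dir = "results/pipeline")),
                    mode = "stats", output_dir = "results/pipeline")
rep <- res$report

cat("Mixed ANOVA:\n")
print(transform(rep$anova, ss = signif(ss, 4), ms = signif(ms, 4),
                F = signif(F, 4), p = signif(p, 4)))
cat("\nBetween-condition comparisons (BH-FDR over the three regions):\n")
print(transform(rep$between_condition[, c("region", "t", "df", "p",
                                          "p_fdr", "cohens_d")],
                t = round(t, 3), p = signif(p, 3), p_fdr = signif(p_fdr, 3),
                cohens_d = round(cohens_d, 3)))
cat("\nOne-sample tests against chance (uncorrected):\n")
print(transform(rep$one_sample[, c("region", "condition", "mean", "sem",
                                   "t", "df", "p", "cohens_d")],
                mean = round(mean, 4), sem = round(sem, 4),
                t = round(t, 3), p = signif(p, 3),
                cohens_d = round(cohens_d, 3)))
cat("\nReport written to", res$report_path, "\n")
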