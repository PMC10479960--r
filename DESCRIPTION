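Package: ovomemri
Title: In Ovo MEMRI T1 Relaxometry and Hemispheric Lateralization Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of manganese-enhanced MRI (MEMRI) of the
    chick embryo brain. Fits the saturation-recovery signal model voxelwise
    to variable-TR (RARE-VTR) acquisitions to obtain T1 maps, aggregates T1
    over manually segmented regions of interest per hemisphere, converts to
    longitudinal relaxation rates, and computes a left-right lateralization
    index per visual region (Wulst, dorsolateral thalamus/Gld, optic
    tectum). Includes the group statistical battery (mixed-design ANOVA,
    FDR-corrected between-condition t-tests, one-sample lateralization
    tests, Cohen's d) and a parametric digital egg-brain phantom generator
    that simulates calibrated cohorts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
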