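# ovomemri

Quantitative analysis of manganese-enhanced MRI (MEMRI) of the chick embryo
brain, for imaging scientists and comparative neuroscientists studying
light-induced hemispheric asymmetry in ovo.

Mn²⁺ accumulates in active neurons and shortens the longitudinal relaxation
time T1 concentration-dependently, so a T1 map acquired after manganese
administration is an activity map. `ovomemri` implements the full chain
from a variable-TR (RARE-VTR) acquisition to group statistics:

* **Voxelwise T1 relaxometry** — nonlinear least-squares fit of the
  saturation-recovery model *S*(TR) = *S*₀(1 − e^(−TR/T1)) (optionally the
  3-parameter *S* = *a* + *b* e^(−TR/T1)) at the 13-point TR schedule
  169.3–4990.6 ms, via variable projection plus vectorised Gauss–Newton,
  with bounds, convergence flags and residual diagnostics.
* **ROI lateralization** — pooled hemispheric mean T1 over the segmented
  sections of the Wulst, dorsolateral thalamus (Gld) and optic tectum,
  rate transform t1 = 1000/T1 (s⁻¹), and the lateralization index
  LI = (L − R)/(L + R) per subject and region (+1 = activity only left,
  −1 = only right).
* **Group statistics** — 2(condition: dark, light) × 3(region) mixed
  ANOVA, per-region between-condition pooled t-tests with
  Benjamini–Hochberg FDR, one-sample tests against chance, Cohen's d.
* **Digital egg-brain phantom** — a parametric 9-slice simulator with
  bilateral section geometry (2 Wulst / 3 thalamus / 4 tectum sections per
  hemisphere), linear Mn-concentration contrast and calibrated
  between-subject index variability, so the whole pipeline is testable
  without scanner data.

File formats: NIfTI-1 volumes with JSON sidecars (`tr_list_ms`, `te_ms`),
ITK-SNAP-compatible integer label maps with a CSV legend
(`label_id, region, hemisphere, section`), CSV manifests/records and a
JSON statistics report.

## Worked example

The numbered drivers under `analysis/` run the workflow end-to-end on a
simulated calibrated cohort (8 dark-incubated, 10 light-exposed subjects,
64 × 64 × 9 grid, SNR 40):

```sh
Rscript analysis/01_simulate.R        # cohort volumes + manifest
Rscript analysis/02_fit_t1_maps.R     # voxelwise T1 maps
Rscript analysis/03_roi_lateralization.R
Rscript analysis/04_group_stats.R
Rscript analysis/05_replicate_pattern.R
```

Stage 3 prints, for one master seed:

```
Measured vs ground-truth index: RMS deviation 0.00289 (per-subject measurement noise at SNR 40)
Group means of the measured index:
                dark   light
optic_tectum  0.0028 -0.0178
thalamus_gld -0.0303 -0.0153
wulst        -0.0002 -0.0164
```

i.e. the fitted indices track each subject's ground truth to ≈ 0.003 at
this SNR, and the dark group shows the strongest (negative = rightward)
thalamic asymmetry. Stage 4 then prints the ANOVA table, the
FDR-corrected between-condition comparisons, e.g.

```
        region      t df      p p_fdr cohens_d
2 thalamus_gld -1.691 16 0.1100 0.123   -0.802
```

and the six one-sample tests (here the dark thalamus is significantly
right-lateralized, t(7) = −4.865, p = 0.0018). Any single 18-subject
cohort is one random draw: stage 5 repeats the experiment over 200
replicate cohorts and reports how often each significance component
recurs, which is the right way to read near-threshold effects.

Programmatic use mirrors the scripts:

```r
library(ovomemri)
coh <- sample_cohort(cohort_spec(master_seed = 1))
s   <- coh$subjects[[1]]
map <- fit_t1_volume(s$series, mask = coh$label_volume > 0)
rec <- build_subject_record(map, coh$label_volume, coh$legend,
                            s$subject_id, s$condition)
rec[rec$region == "thalamus_gld", "lateralization_index"]
```

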