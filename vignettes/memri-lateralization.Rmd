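---
title: "Quantifying embryonic brain lateralization from in-ovo MEMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying embryonic brain lateralization from in-ovo MEMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovomemri)
```

## The measurement problem

Manganese-enhanced MRI (MEMRI) maps accumulated neuronal activity:
paramagnetic Mn²⁺ enters active neurons through voltage-gated calcium
channels and shortens the longitudinal relaxation time T1 of surrounding
water protons in proportion to its local concentration. In the chick embryo
(*Gallus gallus*), light reaching the right eye through the shell during the
late sensitive window (E17–E18) is thought to lateralize activity in the two
visual pathways. `ovomemri` implements the complete quantitative chain from
a variable-TR acquisition to the group-level asymmetry statistics:

1. **Relaxometry** — voxelwise nonlinear least-squares fit of the
   saturation-recovery signal model to a 13-point variable-TR (RARE-VTR)
   magnitude series, yielding T1 maps with convergence diagnostics.
2. **ROI aggregation** — pooled hemispheric mean T1 over the manually
   segmented sections of three visual regions (Wulst, dorsolateral
   thalamus/Gld, optic tectum), transformed to relaxation rates
   `t1 = 1000 / T1` (s⁻¹ for T1 in ms).
3. **Lateralization index** — `LI = (L − R) / (L + R)` on the hemispheric
   rates; +1 means activity confined to the left hemisphere, −1 to the
   right.
4. **Group statistics** — 2(condition: dark, light) × 3(region) mixed
   ANOVA, per-region between-condition pooled t-tests under
   Benjamini–Hochberg FDR, one-sample tests of each cell against chance
   (uncorrected), and Cohen's d throughout.
5. **Digital phantom** — a parametric egg-brain simulator that renders
   calibrated cohorts so that every stage above is testable end-to-end
   without any scanner data.

## Signal model and fitting

The acquisition samples the saturation-recovery curve at repetition times
TR (ms). The default (`sr2`) model is

$$S(\mathrm{TR}) = S_0\,\bigl(1 - e^{-\mathrm{TR}/T_1}\bigr),$$

which matches a magnitude RARE acquisition with constant echo time: TE is
constant across the schedule, so T2 decay is absorbed into $S_0$ and
carried only as sidecar metadata. A 3-parameter variant (`sr3`,
$S = a + b\,e^{-\mathrm{TR}/T_1}$) is selectable to guard against baseline
offsets; on offset-free data its fitted offset $a + b$ vanishes relative to
$S_0$ (tested to $10^{-3}$).

Fitting is plain (Gaussian) least squares. Whether a magnitude-bias-aware
Rician likelihood would be preferable at very low SNR is a known
limitation; at the SNR regime simulated here (≈ 40) the gaussian
approximation is accurate and the median fitted T1 at true T1 = 1000 ms is
within 2% of truth (tested over 600 voxels).

The optimizer exploits the model's structure rather than calling a
general-purpose fitter per voxel:

* **Variable projection grid:** for fixed $T_1$ the model is linear in
  $S_0$, so the profiled residual over a 60-point log-spaced $T_1$ grid in
  [5, 10000] ms is computed for *all* voxels at once by matrix products.
* **Vectorised Gauss–Newton:** from the grid minimum, damped Gauss–Newton
  steps (closed-form 2×2 normal equations per voxel, step-halving when the
  residual would rise) refine $(T_1, S_0)$ simultaneously across voxels,
  stopping when the relative parameter change falls below $10^{-8}$ or
  after 200 iterations.
* **Bounds and sentinels:** $T_1 \in [5, 10000]$ ms,
  $S_0 \in (0, 10 \cdot \max S]$; fits landing on a bound, and all-zero or
  constant signals, are flagged non-converged and carry NA — downstream ROI
  means exclude them (and report voxel counts), so boundary artefacts
  cannot contaminate the averages. No spatial regularisation or smoothing
  is applied anywhere.

On noiseless data the fit recovers T1 to machine precision (the test suite
asserts relative error below $10^{-6}$ across T1 from 200 to 5000 ms at the
13-TR schedule, and equality with an independent Levenberg–Marquardt fit on
noisy voxels).

## Averaging order and the index

Regional hemispheric means are computed on the **T1 scale first** and then
transformed to rates — the voxels of all sections of a (region, hemisphere)
are pooled into one unweighted mean (sections carry no weighting rule, so
voxel pooling is the simplest faithful choice). Mean-then-transform and
transform-then-mean genuinely differ for heterogeneous ROIs (Jensen's
inequality; a test pins the implemented order and the direction of the
difference). Hemisphere identity comes solely from the label legend; the
package never infers left/right from the image.

## The digital phantom

`default_phantom_spec()` builds a 64 × 64 × 9 grid at 0.25 × 0.25 × 1 mm
spacing (the study's in-plane matrix scaled down from 200 × 200 for
desk-scale runtime; the geometry is fully parametric) holding one-slice
ellipsoidal sections per hemisphere: 2 for the Wulst, 3 for the thalamus,
4 for the tectum — the section counts actually quantified per hemisphere —
of ≈ 37 voxels each. Overlapping sections are a hard error, mirroring a
segmentation in which each voxel belongs to at most one label.

Contrast follows the linear fast-exchange model
`R1 = baseline_r1 + relaxivity_r1 × [Mn]`. No relaxivity or absolute
embryonic chick brain T1 was available to calibrate against, so the
defaults — baseline T1 = 1400 ms at 7 T and relaxivity 6 s⁻¹·mM⁻¹ — are
literature-scale placeholder values, not measured ones; the same holds for
the post-Mn region mean rates (1.4, 1.5, 1.6 s⁻¹ for Wulst, thalamus,
tectum). None of the acceptance quantities depend on these absolute
choices: the lateralization index is a rate *ratio*, invariant to global
intensity scaling (tested) and first-order insensitive to the absolute rate
level.

Between-subject variability is injected **at the index level**: per subject
and region an index is drawn from the calibrated normal distribution and
inverted exactly to hemispheric rates
(`L = r̄(1 + LI)`, `R = r̄(1 − LI)`), because the published calibration
targets (group means ± SEM of the index) live on that scale. The
calibration SD is SEM·√n per cell (n = 8 dark, 10 light), which means the
drawn indices subsume measurement noise as observed in the study — the
appropriate level for replicate-cohort Monte-Carlo work, while fully
rendered cohorts add explicit acquisition noise on top.

The acquisition default is the study's 13-TR schedule
(`vtr_tr_schedule()`, 169.3–4990.6 ms, TE 6.25 ms) with $S_0 = 100$ and
gaussian noise σ = 2.5 (SNR 40); Rician noise is available
(`noise_model = "rician"`), the physically correct magnitude model at low
SNR. Per-subject seeds derive from the master seed by the fixed rule
`(master · 1009 + ordinal · 7919) mod (2³¹ − 1)`, so cohorts are exactly
reproducible with independent per-subject noise.

What the phantom deliberately does **not** emulate: k-space/RARE echo-train
effects, B0/B1 inhomogeneity, slice profiles, partial-volume mixing at ROI
edges, motion, or Mn transport kinetics. Passing end-to-end tests therefore
demonstrates the correctness of the estimation chain under the stated
forward model — not robustness to those physics; on real data the ROI
means additionally inherit segmentation and partial-volume error.

## Statistics

The mixed ANOVA uses the univariate decomposition with subjects nested in
condition: condition is tested against the subjects-within-condition mean
square (df 1, N − 2), region and region × condition against the
region × subjects-within-condition mean square (df 2, 2(N − 2)); no
sphericity correction is applied, matching the integer degrees of freedom
reported for N = 18 — F(1,16) and F(2,32). The implementation runs through
`stats::aov` with an `Error(subject/region)` stratum; an explicit
cell-mean sum-of-squares decomposition (`mixed_anova_bruteforce()`) serves
as an independent oracle, and the two agree to $10^{-10}$ on randomized
small designs including unbalanced groups.

Between-condition comparisons use Student's pooled-variance t (df
n₁ + n₂ − 2 = 16 — the pooled rather than Welch form is forced by that
integer df), with BH-FDR applied across exactly the three regional
p-values, the only family the study corrected. One-sample tests against
chance are uncorrected by design. Cohen's d conventions are
`d = mean/sd` (one-sample) and the pooled-SD standardized difference
(two-sample); both satisfy their algebraic identities with t
($d = t/\sqrt{n}$ and $d = t\sqrt{1/n_1 + 1/n_2}$, tested).

## Reproduction behaviour and its limits

With all index SDs set to zero and noiseless acquisition, the full chain
(configured index → rendering → simulation → voxelwise fit → ROI pooling →
index) is the identity to better than $10^{-6}$ — on the default grid the
round-trip error is at machine precision. Calibrated noisy cohorts recover
the dark-thalamus group mean of −0.038 within Monte-Carlo error
(`scripts/acceptance.R` recomputes this end-to-end over 20 replicate
cohorts per condition).

The *significance pattern*, however, is only partially reproducible — and
that is a property of the study conditions, not of the implementation. The
printed effect sizes put two tests near the detection threshold: the
thalamus between-condition contrast (d ≈ 1.27 at n = 8 vs 10, tested under
BH) and the light-Wulst one-sample test (d ≈ 0.75 at n = 10) each have
power in the 50–60% range, while the dark-thalamus lateralization
(d ≈ 2.15) replicates essentially always and the tectum stays silent in
most replicates. The joint event — every component of the reported pattern
in one cohort — therefore recurs in well under half of the replicates.
`analysis/05_replicate_pattern.R` computes these frequencies over 200
calibrated cohorts, and the corresponding acceptance test asserts the
majority criterion honestly (it fails, by design of the study's own effect
sizes, while the calibration assertion passes).

## Problem sizes and numerical choices

The shipped tests and scripts use: the full 64 × 64 × 9 grid (≈ 670 ROI
voxels) for single-subject chain-identity checks and for the end-to-end
acceptance cohorts (360 fitted subjects in ≈ half a minute); a 24 × 24 × 9
grid with radius-2 sections for multi-subject unit tests; 200
generator-level replicate cohorts for the Monte-Carlo calibration and
pattern-frequency studies. Ties in the grid search resolve to the first
(smallest-T1) candidate; empty ROIs raise errors naming region and
hemisphere rather than returning NA; all output tables carry full double
precision, with rounding treated purely as a presentation concern.
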