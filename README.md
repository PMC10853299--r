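# rimsift

Quantitative analysis of **deeply hypointense voxels on normalized 3-D
T1-weighted MRI** as a surrogate marker for **phase-rim lesions (PRLs)** in
multiple sclerosis.

PRLs — lesions ringed by iron-laden microglia on susceptibility-weighted
phase imaging — mark chronic "smoldering" inflammation and progressive
disease, but SWI is rarely part of follow-up protocols and the rims are
hard to read. On a Nyúl–Udupa-normalized 0–100 T1 intensity scale, pooled
PRL voxels are bimodal (modes ≈ 0.9 and 60.2, ~14% of mass in the
hypointense mode) while ordinary non-phase-rim white-matter lesions
(nPR-WMLs) are unimodal (mode ≈ 64.8, ~0.5% of voxels below the inter-mode
cutoff of 25). Lesion-wise, the 5th percentile (p5) of a lesion's
normalized pre-contrast T1 intensities separates the classes: predict PRL
iff

&nbsp;&nbsp;&nbsp;&nbsp;p5(lesion) < c,&nbsp;&nbsp; c chosen on training
data to maximize sensitivity subject to specificity ≥ 0.95.

The package is aimed at neuroimaging researchers who want to reproduce,
stress-test or extend this analysis. It implements every stage as tested,
reusable R code:

| stage | functions |
|---|---|
| synthetic ground-truth phantom (MRI volumes + lesion masks) | `phantom_spec()`, `generate_phantom()`, `sample_lesion_intensities()` |
| NIfTI I/O, masks, grid checks | `read_volume()`, `write_volume()`, `binarize()`, `check_compatible()` |
| piecewise-linear histogram-matching normalization | `train_template()`, `apply_template()`, `save_template()` |
| lesion isolation and per-lesion features | `subtract_prl()`, `label_components()`, `extract_features()`, `filter_lesions()` |
| voxel-wise group histograms, modes, deep fractions, rank-sum test | `group_histogram()`, `detect_modes()`, `deep_fraction()`, `wilcoxon_rank_sum()` |
| specificity-constrained p5 classifier | `stratified_split()`, `select_cutoff()`, `evaluate()`, `fisher_exact()` |
| one-call reproducible pipeline | `run_config()`, `run_all()` |

## A worked example

The default phantom reproduces the study conditions: 39 PRLs and 1075
nPR-WMLs (plus 8 contrast-enhancing and 8 sub-1 mm³ lesions that the
exclusion filters must remove) on a 192³ grid of isotropic 0.5 mm voxels.

```r
library(rimsift)
report <- run_all(run_config(seed = 2026L))
report
#> <prl_report> config 21645803, seed 2026
#>   lesions: 39 PRL + 1091 nPR-WML components; 1114 kept after filters (8 too small, 8 enhancing)
#>   voxel-wise: PRL bimodal (modes  0.05, 62.25), nPR-WML unimodal (mode 64.5); deep fractions 0.135 / 0.0049 below 25
#>   p5 rank-sum p = 1.33e-21
#> <p5_cutoff> predict PRL iff p5 < 26.66 (training sens 0.900, spec 1.000 >= 0.95)
#> <confusion_metrics> tp 19, fn 0, fp 0, tn 537
#>   sensitivity 1.000, specificity 1.000, ppv 1.000, npv 1.000, f1 1.000
#>   Fisher exact p = 1.16e-35
```

Reading the output:

* all 1130 planted lesions are recovered as connected components, and the
  filters remove exactly the 8 tiny (volume < 1 mm³) and 8 enhancing
  (mean post-contrast intensity > 80) lesions, leaving the 39 + 1075
  analysis sample;
* the voxel-wise stage reports the designed histogram structure — bimodal
  PRL, unimodal nPR-WML — with deep-voxel fractions near the generative
  14% / 0.5%;
* the stratified 50% split gives 20/538 training and 19/537 test lesions;
  the fitted cutoff satisfies its 0.95 training-specificity constraint;
* on phantoms the classes separate almost perfectly — real lesions, with
  partial-volume voxels and irregular geometry, are harder, which is why
  the published test sensitivity is far from 1.

Pass `out_dir =` to `run_config()` to write normalized volumes, templates,
the lesion table, histograms, a JSON report and a run log; identical
configurations produce byte-identical reports.

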