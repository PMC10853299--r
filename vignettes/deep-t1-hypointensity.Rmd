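---
title: "Deep T1 hypointensity as a phase-rim lesion marker: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep T1 hypointensity as a phase-rim lesion marker: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rimsift)
```

## The problem and the model

Phase-rim lesions (PRLs) are multiple-sclerosis lesions with a paramagnetic
rim on susceptibility-weighted phase imaging, a proposed marker of chronic
"smoldering" inflammation and progressive disease. They are hard to find:
SWI is not part of routine follow-up protocols and the rims are subtle.
On intensity-normalized 3-D T1-weighted images, however, PRLs carry a
population of *deeply hypointense* voxels that ordinary non-phase-rim
white-matter lesions (nPR-WMLs) essentially lack. Two observations drive
the whole package:

* **Voxel-wise**: pooled PRL voxel intensities are bimodal — a hyperintense
  mode near 60.2 on the normalized 0–100 scale and a hypointense mode near
  0.9 holding roughly 14% of the mass — while pooled nPR-WML intensities
  are unimodal around 64.8, with only ~0.5% of voxels below the inter-mode
  cutoff of 25.
* **Lesion-wise**: the 5th percentile (p5) of a lesion's normalized
  pre-contrast T1 intensities summarizes its hypointense tail while
  resisting single-voxel outliers. A lesion is called a PRL when its p5
  falls strictly below a threshold chosen on training data under a
  specificity constraint.

The classifier is deliberately primitive — one feature, one threshold — so
its value lies in the calibration and evaluation protocol around it, all of
which this package reproduces end to end on synthetic data.

## The phantom: what it emulates and what it does not

Patient images cannot ship with a package, so every stage runs against a
phantom (`phantom_spec()`, `generate_phantom()`) that reproduces the
*statistical* structure the analysis depends on:

* co-registered isotropic 0.5 mm pre- and post-contrast volumes sharing one
  grid and affine;
* lesions planted as rasterized spheres (a voxel belongs to a lesion iff
  its centre lies within the sampled radius), mutually separated by at
  least one background voxel so connected components coincide with planted
  lesions at any connectivity;
* severe class imbalance at the study scale: 39 PRLs vs 1075 nPR-WMLs by
  default, plus 8 contrast-enhancing and 8 sub-1 mm³ lesions to exercise
  the exclusion filters;
* class-conditional intensities: nPR-WML voxels from N(64.8, 15.45); PRL
  voxels from the mixture 0.14·N(0.9, 3) + 0.86·N(60.2, 8), with the
  hypointense component assigned to each lesion's outermost voxels first,
  giving a rim-like shell (the outer third of the radius in the typical
  draw) while keeping the overall hypointense fraction binomial;
* enhancing lesions identical pre-contrast but bright (N(90, 5)) on the
  post-contrast volume.

**Calibration.** Only the modes (0.9, 60.2, 64.8) and the hypointense
weight (14%) are externally specified; the standard deviations are the
package's own calibration, chosen once so that the analytic mass below the
intensity-25 cutoff matches the reported deep-voxel fractions: sd 15.45
puts 0.50% of the nPR-WML Gaussian below 25, and the PRL mixture above has
14.00% of its mass below 25. The background is a four-component tissue
mixture (CSF-like N(7,5) at weight 0.12, grey-matter-like N(45,8) at 0.38,
white-matter N(70,6) at 0.46, and a bright compartment N(96,6) at 0.04)
whose brain-wide 1st/99th percentiles land near 0 and 100 — that makes the
phantom "born normalized", so a self-trained template is close to the
identity and generative means survive normalization for recovery tests.

**What the phantom does not model**: brain anatomy, partial-volume
effects, spatially correlated noise, SWI phase contrast, scanner drift.
Passing tests therefore demonstrate that the *pipeline* recovers known
structure from data obeying its assumptions — not that the biological
effect exists, which only the clinical data can show.

## Intensity normalization

`train_template()` / `apply_template()` implement piecewise-linear
histogram matching (the Nyúl–Udupa standard scale). Landmarks default to
the method's canonical configuration — deciles anchored by the 1st and
99th percentiles — mapped to a 0–100 standard scale; the reported
intensities (64.8, 80, 42.133) are only meaningful on such a scale.
Details that matter:

* **Pinned percentile estimator.** All percentiles everywhere (landmarks,
  the p5 feature, oracles) use linear interpolation between closest order
  statistics at index (n−1)·p/100 (`landmark_quantile()`), so results are
  bit-reproducible across modules.
* **Extrapolation, not clipping.** Voxels beyond the p1/p99 landmarks are
  mapped by extending the first/last segment linearly. Clipping would
  collapse the deep-hypointensity tail — the very signal under study.
* **Brain mask convention.** The normalization mask defaults to the
  image's nonzero voxels, the usual convention for brain-extracted images;
  phantoms are all-brain by construction.
* **Exactness.** For a template trained on a single image the knots are
  collinear by construction, the voxel map is globally affine, and
  post-normalization landmarks equal the standard values to float
  precision (the package tests assert 1e-6). For multi-image templates the
  agreement is limited by order-statistic spacing around each landmark
  times the slope change across it; tests use correspondingly realistic
  tolerances.
* The map is monotone and exactly invariant to affine rescaling of the
  input (landmarks transform covariantly), which is what makes the
  distortion-recovery experiment below meaningful.

## Lesion isolation and features

`subtract_prl()` removes PRL voxels from the total lesion map;
`label_components()` isolates lesions by 3-D connected components
(default 26-connectivity, the common 3-D clustering default; 6 and 18 are
available since the choice is a convention, not a result). Labels are
assigned in order of each component's first voxel in column-major grid
order, making label numbering deterministic. Per lesion,
`extract_features()` records voxel count, physical volume, mean normalized
post-contrast intensity and the p5 normalized pre-contrast intensity.

`filter_lesions()` applies the two exclusion rules with strict
boundaries — volume strictly under 1 mm³, mean post-contrast intensity
strictly greater than 80 — attributed sequentially (volume first) so each
removed lesion counts under exactly one rule. At 0.5 mm spacing the volume
rule removes exactly the 1–7-voxel clusters the phantom plants as "tiny".

## Voxel-wise histogram analysis

`group_histogram()` bins each group's voxel intensities into half-open
0.1-wide bins with heights as *percent of group voxels*, so wildly
imbalanced groups overlay comparably. `detect_modes()` smooths with a
centred moving average and keeps the tallest local maxima as modes, with
three determinism/robustness rules:

* plateau ties collapse to the lower intensity;
* a second mode must span at least 5 bins inclusive of both mode bins,
  reach at least 5% of the primary mode's smoothed height (an isolated
  sampling spike over an empty valley is not a mode), and be separated by
  a valley dipping below half the smaller mode's height;
* the inter-mode minimum is the lowest smoothed bin strictly between the
  mode bins, ties to the lower intensity.

**Choosing the smoothing window.** The default (5 bins = 0.5 intensity
units) matches the 0.1-precision at which mode locations are reported, but
the argmax of a smoothed histogram can only localize a peak to roughly the
scale at which curvature exceeds counting noise. For the broad Gaussians
here (sd 8–15.45) that means ±2–3 units at 10⁵ samples with a 5-bin
window. Parameter-recovery tests therefore match the window to the peak
width — 51 bins for the PRL mixture at 10⁵ voxels, 151–301 bins and up to
10⁶ voxels for the very flat sd-15.45 nPR-WML peak — which is unbiased for
these symmetric peaks and empirically localizes all modes to within ±1.
The per-group deep-voxel fraction (`deep_fraction()`, strictly below the
cutoff) is estimator-free and needs no such care.

`wilcoxon_rank_sum()` contrasts the two groups' lesion-wise p5 values:
exact null enumeration when the combined sample is ≤ 20 without ties,
otherwise a normal approximation with midranks and tie correction and no
continuity correction (so identical samples give p = 1 exactly).

## The classifier

`stratified_split()` halves each class separately (ceiling allocation puts
an odd class's extra lesion in training — 39 PRLs always split 20/19).
`select_cutoff()` evaluates every midpoint between consecutive sorted
unique p5 values (plus sentinels beyond the extremes), keeps the
candidates whose *training* specificity meets the constraint (default
0.95, exposed as a parameter since only the achieved test specificity of
0.959 is reported externally), and maximizes sensitivity, breaking ties
towards higher specificity and then the lower cutoff. The decision rule is
strictly below-threshold: a lesion at the cutoff is negative. When a ±∞
sentinel wins, the stored cutoff is the finite value just outside the
observed range inducing the same rule. `evaluate()` computes the confusion
matrix, the five derived proportions (zero-denominator metrics are NaN and
flagged by name, never silently 0), and a Fisher exact test on the matrix.

The split is lesion-level, mirroring the published design; lesions from
one patient can land on both sides of a real-data split, a leakage caveat
that synthetic phantoms do not exhibit (their lesions are independent) but
that matters when applying the pipeline to clinical cohorts.

## Numerical and reproducibility choices

* All randomness flows through explicit integer seeds; the pipeline seed
  propagates to the phantom and (offset by one) to the split, and every
  generator call restores the caller's RNG state.
* Reports carry an FNV-1a hash of the configuration and no timestamps, so
  an identical `run_config()` reproduces a byte-identical `report.json`.
* Degenerate inputs fail loudly: NaN voxels on read, constant images at
  normalization, empty masks at histogramming, single-class tables at
  splitting, infeasible specificity constraints at fitting.
* Problem sizes in the test-suite: unit tests run 48³–72³ phantoms with a
  few dozen lesions; the distortion-recovery experiment uses a 160³
  phantom with 150 PRLs and 400 nPR-WMLs (≈10⁶ lesion voxels) so group
  modes are estimable to ±1; the end-to-end check runs the full 192³
  default phantom (39 + 1075 + 8 + 8 lesions) twice to confirm
  reproducibility.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(seed = 2026L)
report <- run_all(cfg)
report
```

On the default phantom this prints, among other things, a bimodal PRL
group histogram and a unimodal nPR-WML histogram, deep-voxel fractions
near 0.14 and 0.005, a training specificity at or above the 0.95
constraint, and filter removal counts equal to the planted tiny and
enhancing lesions (8 and 8).

## Known limitations

* Spherical lesions and i.i.d. voxel noise are idealizations; real lesion
  geometry, partial-volume voxels and spatially structured noise will
  loosen the separation between the classes.
* The rim geometry (hypointense component outermost) is a modelling
  convenience — the deep-voxel *fraction*, not its spatial arrangement, is
  what the downstream statistics consume.
* Mode locations from histogram argmax are estimator-dependent; treat the
  reported modes as descriptive, and the deep-voxel fractions and p5
  classifier as the quantitative outputs.
* The specificity constraint value and the exact landmark configuration of
  the original normalization templates are conventions adopted here, not
  externally fixed facts; both are parameters.
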