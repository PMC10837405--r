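---
title: "Histogram-based lesion quantification on amino-acid PET: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Histogram-based lesion quantification on amino-acid PET: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suvhist)
```

## The model

A lesion ROI on an amino-acid PET scan contains a set of voxel SUVs
$X(i),\ i = 1..N_p$. The working model is that proliferating tumor tissue,
despite regional heterogeneity, produces an approximately symmetric
(Gaussian-like) SUV distribution, while non-neoplastic tissue — necrosis,
inflammation, treatment effect — produces a left-peaked distribution with a
long right tail. Two first-order statistics of the raw voxel series capture
this:

$$\mathrm{skewness} \;=\;
\frac{\tfrac{1}{N_p}\sum_i \bigl(X(i)-\bar X\bigr)^3}
     {\Bigl(\sqrt{\tfrac{1}{N_p}\sum_i \bigl(X(i)-\bar X\bigr)^2}\Bigr)^{3}},
\qquad
\mathrm{tendency} \;=\; \mathrm{SUV}_{mean} - \mathrm{SUV}_{median}.$$

Skewness is dimensionless; tendency is in SUV units. A lesion is called
non-neoplastic when the deciding feature strictly exceeds its threshold.
Neither statistic sees spatial structure: they are order-invariant functions
of the voxel multiset, which is why the pipeline never resamples images and
only ever resamples *masks*.

### Estimator choices

* Skewness uses the **population (divide-by-$N_p$) estimator**, with no
  Fisher–Pearson small-sample correction. That is the definition as used
  clinically, and with ROI sizes of $10^2$–$10^3$ voxels the correction
  factor is negligible anyway. `suv_skewness()` implements exactly this
  formula; the suite checks it against an explicit-loop brute-force oracle
  and against `e1071::skewness(type = 1)` at $10^{-10}$.
* A zero-variance series has undefined skewness: the function returns `NaN`
  with a warning, never a silent 0, and the classifier then *abstains*
  rather than guessing.
* The median of an even-length series is the **midpoint of the two central
  order statistics** — the standard convention, and deterministic.
* TLA is computed as $\sum_i X(i) \cdot v$ (voxel volume $v$ in mL), which is
  algebraically $\mathrm{SUV}_{mean}\cdot\mathrm{MTV}$ but conserves total
  activity exactly in floating point.

## Geometry

All spatial reasoning happens in world millimetres through each grid's
voxel-to-world affine (RAS+). Design choices where the underlying procedure
is usually left unstated:

* **Voxel membership**: a voxel belongs to a region iff its *center* lies
  inside (sphere rasterization uses an inclusive boundary). Simple,
  deterministic, and checkable against a brute-force distance scan — which
  the tests do, exactly, on axis-aligned and anisotropic grids.
* **Mask resampling** between grids is nearest-neighbor through world
  coordinates, so binary masks stay binary. Identity on identical grids.
  Features are always computed on the native PET grid.
* **Reference regions** are three 1 cm spheres in normal brain. They can be
  given explicitly in world coordinates (placement is manual in clinical
  practice) or auto-mirrored: the lesion centroid is reflected across the
  midsagittal plane (default: the volume's world-x midplane, overridable via
  `x_mid` since real head placement is rarely centered) and the second and
  third spheres are offset ±12 mm along the superior–inferior axis. The
  dispersion scheme is this package's convention — any scheme yielding
  disjoint normal-brain spheres is equally defensible. N$_{max}$ and
  N$_{mean}$ are computed on the **pooled union** of the three sphere voxel
  sets, matching the convention of quoting single normal-brain values from
  three ROIs.
* **SUV normalization** is body-weight SUV with weight in grams:
  $\mathrm{SUV} = A\,[\mathrm{Bq/mL}] \cdot w\,[\mathrm{g}] /
  (D\,[\mathrm{Bq}]\cdot f)$. The decay factor $f \in (0,1]$ is an explicit
  input rather than computed from a half-life internally, because acquisition
  protocols differ in whether they correct to injection or scan-start time;
  keeping it as data makes the applied correction auditable.

## Classification

The rule is `value > threshold` → non-neoplastic, with defaults skewness
0.624 and tendency 0.084 SUV. Two conventions worth stating:

* **Ties**: a value exactly at the threshold is called neoplastic (strict
  inequality).
* **Combining features**: the default mode is `skewness_only`. The two
  features can genuinely disagree — a necrotic core can show skewness ≈ 1.0
  with tendency still below 0.084 — and skewness is the primary
  discriminator; `tendency_only`, `either` and `both` are exposed for
  sensitivity analysis, and per-feature votes are always reported.

### Where the default thresholds come from, and deriving your own

The default cuts are published clinical calibration constants whose original
derivation (ROC-based? on which subjects?) is not reported. The package
therefore treats them strictly as configuration and offers two transparent
re-derivations from a user's own cohort: the midpoint of the two group means,
and the empirical Youden-optimal cut (maximizing sensitivity + specificity −
1 over observed values, calling the higher-mean group positive at
`value >= cut`, smallest cut among ties). On summary statistics matching the
published group means, midpoint-of-means gives 0.540 (skewness) and 0.062
(tendency) — *not* the published 0.624/0.084 — and the cohort report flags
this explicitly rather than letting the numbers pass as reproduced: without
patient-level data the published cuts cannot be re-derived, only applied.

## Cohort statistics

Group summaries use the sample (n−1) standard deviation, matching the
mean ± SD convention of clinical tables. Two tests are always reported side
by side, because small cohorts genuinely warrant the non-parametric choice
while clinical tables are often captioned with the parametric one:

* Wilcoxon rank-sum, exact when the pooled sample is ≤ 25 and tie-free
  (verified in the tests against exhaustive enumeration of rank
  assignments), otherwise the normal approximation with tie correction;
* Welch's unequal-variance t test — group variances of these features are
  typically unequal, so the pooled-variance form is never used.

No multiple-testing correction is applied: with two histogram features this
mirrors how such tables are reported, and readers can Bonferroni-correct
trivially if desired.

## The synthetic phantom generator

Patient images cannot be redistributed, so validation runs on synthetic 3D
phantoms that reproduce the *statistical* structure the method relies on:

* low uniform normal-brain background: truncated-at-zero Gaussian, mean 0.1
  SUV, SD 0.01 — giving pooled-reference N$_{max}$ ≈ 0.125 and hence T/N ≈ 20
  for a lesion with SUVmax ≈ 2.5, the contrast regime of a clean-background
  amino-acid tracer;
* neoplastic lesions: i.i.d. Gaussian voxel SUVs, default mean 1.1, SD 0.4,
  population skewness exactly 0, per-subject SUVmax landing near 2.5;
* non-neoplastic lesions: i.i.d. gamma voxel SUVs with shape 4.57 and mean
  0.9, chosen because the population skewness $2/\sqrt{\text{shape}}
  \approx 0.936$ sits at the center of the non-neoplastic group's reported
  skewness distribution — the gamma law was preferred over a skew-normal
  precisely because its skewness is closed-form, enabling exact
  parameter-recovery oracles;
* ring + core lesions: an outer Gaussian shell (default mean 1.2, SD 0.3)
  around a low-mean gamma core (mean 0.5), giving a dual-peaked whole-lesion
  histogram that the sub-region masks split into two single peaks;
* cohorts (default 18 neoplastic + 3 non-neoplastic, the group sizes the
  analysis is designed around): per-subject lognormal jitter on the law
  parameters (sdlog 0.2 on the Gaussian mean, 0.3 on its SD; 0.2 on gamma
  shape, 0.25 on its mean), lesion radii uniform on 9–20 mm (volumes of a
  few to ~30 mL), centers jittered a few mm. Everything descends from one
  master seed; identical seeds give bit-identical cohorts.

The default grid is 96 × 96 × 60 at 2 mm isotropic: a 15 mm lesion then
covers ≈ 1700 voxels, so the sampling SD of its skewness,
$\sqrt{6/N_p} \approx 0.06$, is well below the group separation of ≈ 0.9.

### What the generator does *not* emulate

Lesion voxels are i.i.d.: there is no spatial texture, no PSF blur, no
Poisson count noise, no reconstruction artifact, no partial-volume effect.
Because every feature in the package is order-invariant, spatial correlation
would add realism but no additional testable signal. Passing tests therefore
demonstrate that the *computational pipeline* is correct and that the
decision rule behaves as intended under the assumed intensity model — they
are not evidence about patient populations, scanner physics, or the clinical
accuracy of the thresholds.

Sampling is clipped at zero after drawing. For the default Gaussian law
about 0.3 % of lesion voxels clip, which biases estimated skewness upward by
roughly +0.03 — visible in the recovery measurements, and an order of
magnitude below both the sampling tolerance $2\sqrt{6/N_p}$ and the group
separation, so it is accepted rather than corrected.

## Numerical and I/O choices

* Volumes are float64 in memory and float32 on disk (NIfTI-1 via RNifti,
  sform and qform both set): PET dynamic range makes this lossless in
  practice, and affines with millimetre-scale entries round-trip exactly.
* Voxel series are collected in ascending linear (column-major) index order —
  irrelevant to every statistic, fixed for reproducibility.
* The display histogram uses 64 uniform bins on the fixed range [0, 4];
  out-of-range voxels accumulate into the terminal bins with a warning so
  counts always sum to $N_p$. Bin count is a display knob only: skewness and
  tendency are computed from raw voxels, never from counts.
* Degenerate inputs fail loudly with classed conditions
  (`suvhist_empty_roi_error`, `suvhist_grid_error`, …); a failing subject in
  a cohort run is recorded and skipped, and the run continues.

## Validation problem sizes

The shipped suite validates, among other things: skewness against a
brute-force oracle on 1000 random series; sphere rasterization against a
full-grid distance scan; exact rank-sum p-values against exhaustive
enumeration; skewness recovery on 200 default-size phantoms per law (mean
absolute bias within $2\sqrt{6/N_p}$ of the closed-form truth); and group
separation on 100 independently seeded default cohorts (direction correct in
all, rank-sum p < 0.05 in ≥ 90 %). These sizes were chosen so the complete
suite runs in about two minutes on one CPU while keeping Monte-Carlo noise
far below every asserted margin.

## Known limitations

* Masks are inputs: lesion delineation (e.g. the gross-total-resection
  definition drawn on MRI) and image co-registration happen upstream.
* The thresholds ship as constants from an external calibration on a small
  cohort (3 non-neoplastic subjects); they should be revalidated before any
  use beyond sensitivity analysis.
* Histogram-based separation presumes segmentation on a modality other than
  PET itself — thresholding the PET image would truncate the voxel
  distribution and manufacture skewness.
* No DICOM ingestion, no dynamic (4D) PET, no partial-volume correction.
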