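# suvhist

Intensity-histogram analysis of amino-acid PET for separating neoplastic from
non-neoplastic brain lesions.

## The problem

Radiation necrosis, pseudo-progression and inflammation can take up
amino-acid PET tracers as avidly as tumor. The traditional metabolic
parameters — SUVmax, SUVmean, metabolic tumor volume (MTV), total lesion
activity (TLA) and the tumor-to-normal-brain ratio (T/N) — often cannot tell
the two apart, yet the treatment consequences are opposite. What does differ
is the *shape* of the voxel-value distribution inside the lesion ROI:
proliferating tumor shows a symmetric, roughly Gaussian SUV histogram, while
non-neoplastic lesions show a left-peaked distribution with a long right
tail.

`suvhist` quantifies that shape with two first-order statistics computed from
the raw voxel series X(i), i = 1..Np inside the ROI:

**Skewness** — the population (divide-by-Np) third standardized moment,

```
skewness = ( (1/Np) Σ (X(i) − X̄)³ ) / ( sqrt( (1/Np) Σ (X(i) − X̄)² ) )³
```

**Tendency** — the mean–median shift, in SUV units,

```
tendency = SUVmean − SUVmedian
```

Both are near 0 for symmetric (neoplastic) uptake and positive for
right-skewed (non-neoplastic) uptake. A lesion is called non-neoplastic when
the deciding feature strictly exceeds its threshold (defaults: skewness
0.624, tendency 0.084 SUV; skewness decides by default).

Around this core the package provides: NIfTI SUV-map I/O and body-weight SUV
normalization, lesion/sub-region mask handling with nearest-neighbor
resampling between grids, 1 cm contralateral reference spheres (explicit or
auto-mirrored across the midsagittal plane), cohort-level group comparison
(exact Wilcoxon rank-sum and Welch t tests side by side), candidate threshold
derivation, and a synthetic 3D phantom generator whose lesion intensity laws
have closed-form population skewness — so the entire pipeline can be
validated end-to-end against exact ground truth without any patient data.

## Worked example

Two synthetic subjects on the default 96 × 96 × 60 grid (2 mm voxels,
background ≈ 0.1 SUV): one with symmetric Gaussian lesion uptake
(mean 1.1, SD 0.4 — tumor-like), one with gamma-law uptake
(shape 4.57, mean 0.9 — necrosis-like, population skewness 2/√4.57 ≈ 0.94):

```r
library(suvhist)

tumor    <- make_phantom(phantom_spec(seed = 42))
necrosis <- make_phantom(phantom_spec(law = law_gamma(shape = 4.57, scale = 0.9 / 4.57),
                                      group = "non-neoplastic", seed = 42))

run_subject(tumor,    subject_id = "tumor-like")
#> <subject_result> tumor-like
#>   lesion   SUVmax 2.54  skewness -0.009  tendency +0.001  -> neoplastic
run_subject(necrosis, subject_id = "necrosis-like")
#> <subject_result> necrosis-like
#>   lesion   SUVmax 3.27  skewness +0.960  tendency +0.059  -> non-neoplastic
```

Both lesions are tracer-avid (the tumor-like one has SUVmax 2.54, SUVmean
1.10, MTV 13.9 mL, TLA 15.3 mL·SUV, T/N 20.4 — numbers a traditional
work-up could not separate from the necrosis-like subject), but the histogram
statistics split them cleanly: skewness −0.01 vs +0.96 against the 0.624
threshold.

Cohort level — simulate 18 neoplastic + 3 non-neoplastic subjects and
compare groups:

```r
res <- run_cohort(make_cohort(seed = 7))
res$report
```

prints the two familiar tables (traditional parameters, then histogram
parameters; mean ± SD per group with rank-sum and t-test p-values), e.g.
`skewness 0.076 ± 0.139 vs 0.949 ± 0.185, rank_sum_p 0.0015` — the
traditional parameters do not separate the groups, skewness and tendency do.

Classification also works on bare feature tables, no images needed:

```r
classify_table(data.frame(skewness = c(1.019, -0.043), tendency = c(0.064, -0.017)))
#>   skewness tendency          label  skewness_vote tendency_vote
#> 1    1.019    0.064 non-neoplastic non-neoplastic    neoplastic
#> 2   -0.043   -0.017     neoplastic     neoplastic    neoplastic
```

A thin command-line front end with `simulate`, `features`, `cohort` and
`classify` subcommands lives in `inst/cli/suvhist.R`.

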