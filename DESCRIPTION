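Package: suvhist
Title: Intensity-Histogram Analysis of Amino-Acid PET for Brain Lesion Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies brain lesions on amino-acid PET from standard-uptake-value
    (SUV) maps and co-registered region-of-interest masks. Computes traditional
    metabolic parameters (SUVmax, SUVmean, metabolic tumor volume, total lesion
    activity, tumor-to-normal brain ratio), first-order intensity-histogram
    features (skewness and tendency, the mean-minus-median shift), and classifies
    lesions as neoplastic or non-neoplastic by thresholding the histogram
    features. Includes contralateral reference-sphere handling, nearest-neighbor
    mask resampling between grids, cohort-level group comparisons (exact Wilcoxon
    rank-sum and Welch t tests), threshold derivation utilities, and a synthetic
    3D phantom generator with closed-form ground-truth skewness for end-to-end
    validation of the pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
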