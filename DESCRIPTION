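Package: fmriqc
Title: Single-Subject FMRI Quality Control Metrics, Artifact Detectors, and
    Group Review Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the quantitative quality-control measures used in
    single-subject FMRI pipeline review: motion Euclidean norm and censoring,
    voxelwise outlier fractions, temporal signal-to-noise ratio (TSNR) maps and
    per-region shape/TSNR tables with graded warnings, global/radial/seed-based
    correlation maps, degree-of-freedom accounting including bandpass costs,
    left-right flip detection via a local Pearson correlation cost, variance-line
    and pre-steady-state artifact detectors, a portable static HTML report with
    block ratings, and group summary tables with criterion-based subject
    filtering. A synthetic phantom generator provides ground-truth test data for
    every detector.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
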