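# fmriqc

Quantitative quality control for single-subject FMRI, for researchers who
need to understand a dataset — and decide whether to keep it — from raw EPI
through regression-stage residuals. The package computes the standard review
quantities and artifact checks of a single-subject pipeline, assembles them
into a machine-readable review dictionary and a portable static HTML report,
and tabulates/filters them across subjects with scriptable exclusion
criteria. A synthetic phantom generator with ground-truth artifact records
makes every detector testable offline.

## What it computes

- **Motion and censoring** — the per-volume motion magnitude
  `e[t] = sqrt(sum_k (p_k[t] − p_k[t−1])²)` over the six rigid-body
  parameters (reset per run), a robust voxelwise outlier fraction
  (Legendre detrend, MAD-scaled threshold `Φ⁻¹(1 − 0.001/2T)·1.4826·MAD`),
  censor vectors at configurable limits (defaults: enorm 0.3, outlier
  fraction 0.05, previous-volume extension on), and before/after-censoring
  distribution statistics.
- **Correlation structure** — GCOR (the mean of all pairwise in-mask series
  correlations, computed via the unit-norm identity `‖mean(û_v)‖²`),
  corr_brain (each voxel vs the mean residual), radial correlation (each
  voxel vs its Gaussian-weighted neighborhood average, FWHM 20 mm), seed
  maps, and mask Dice.
- **TSNR** — `mean(signal)/sd(noise)` maps at the volume-registration and
  regression stages, plus a per-ROI table (Nvox, Nzer, Dvox erosion depth,
  TSNR quartiles) with graded warning levels.
- **DF accounting** — `total = censored + regressors + left`, including the
  Fourier cost of bandpassing (2 DFs per removed frequency, 1 at Nyquist):
  retaining only 0.01–0.1 Hz costs 62.5% of the DFs of a 200-volume TR 2 s
  run and 80.5% at TR 1 s.
- **Artifact detectors** — left-right flip checking by comparing the local
  Pearson correlation alignment cost `−Σ w_b·sign(r_b)·r_b² / Σ w_b` of the
  EPI as-is vs mirrored; through-slice variance-line detection; pre-steady-
  state volume counting; design-matrix collinearity warnings. Warnings are
  graded none < undecided < mild < medium < severe.
- **Reporting** — a ten-block relocatable HTML report (vorig, ve2a, va2t,
  vstat, mot, mecho, regr, radcor, warns, qsumm) with montages, percentile/
  alpha thresholding, a similarity-ordered grayplot, block ratings
  (good/bad/other) stored as JSON, group tables, and VARY/EQ/GT/LT/GE/LE
  filtering including `'FINAL rating' EQ bad`.

## Worked example

Simulate the default phantom subject (TR 2 s, 200 volumes, baseline 1000,
noise sd 10, one 1 mm motion spike at volume 60, one variance line, one
seeded network, two pre-steady-state volumes) and run the full QC pipeline:

```r
library(fmriqc)
spec <- simSpec(seed = 7L, presteady_n = 2L)
sim  <- simulateEpi(spec)
res  <- runSubjectQc(sim$epi, sim$anat, sim$mask, sim$truth$motion,
                     atlas = makeToyAtlas(sim$mask, 4L),
                     stim_onsets = list(c(20, 120, 260), c(60, 200, 330)),
                     stim_durations = list(20, 20),
                     out_dir = "QC_demo", subject = "demo")
res$review
which(res$censor@keep == 0)
```

```
ReviewDict with 20 entries
  software version : fmriqc 0.1.0
  num runs found : 1
  num TRs per run : 200
  num TRs per run (applied) : 195
  num TRs per run (censored) : 5
  fraction censored per run : 0.025
  TRs total (uncensored) : 200
  TRs total : 195
  TRs censored : 5
  censor fraction : 0.025
  ...
[1]  1  2 59 60 61
```

The censor caught exactly the injected artifacts: the two pre-steady-state
volumes (1, 2) and the motion spike at volume 60 together with its
neighbors (the forward difference implicates volumes 59 and 61, and the
spike volume itself trips the outlier-fraction limit). Further down the
dictionary, `degrees of freedom left : 184` out of 200 (5 censored, 6
motion + 3 drift + 2 stimulus regressors), `flip guess : NO_FLIP`, and the
raw-series `TSNR average : 49.1` — roughly half the artifact-free value of
100, because the uncensored spike and pre-steady volumes inflate every
voxel's temporal sd, which is exactly the kind of effect the report is
meant to surface. `QC_demo/index.html` holds the ten QC blocks with the
"warns" label colored by the maximum warning level (here medium, from the
variance line and pre-steady checks), and

```r
rateBlock("QC_demo", "demo", "FINAL", rating = "bad")
tab <- buildGroupTable(list(readReviewDict("QC_demo/out.ss_review.demo.json", "json")), "demo")
filterReport(tab, list(criterion("FINAL rating", "EQ", "bad")))$subject
#> [1] "demo"
```

feeds the rating into group-level exclusion filtering. A thin CLI wraps the
same functions: `fmriqc build`, `fmriqc rate`, `fmriqc review-table
--report-outliers "'TSNR average' LT 100"`, and `fmriqc gtkyd` for the
raw-header consistency scan (see `inst/exec/fmriqc`).

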