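---
title: "Quality-control metrics for single-subject FMRI: models, conventions, and phantom validation"
author: "fmriqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-control metrics for single-subject FMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmriqc)
```

# Scope

`fmriqc` computes the quantitative side of single-subject FMRI quality
control: per-volume motion and outlier summaries with censoring, temporal
signal-to-noise (TSNR) maps and per-region tables, global/radial/seed
correlation maps, degree-of-freedom (DF) bookkeeping, and a set of artifact
detectors (left-right flips, through-slice variance lines, pre-steady-state
volumes, design-matrix collinearity). The results are merged into an ordered
review dictionary, rendered into a portable static HTML report with graded
warnings and block ratings, and tabulated across subjects with
criterion-based exclusion filtering. Registration, regression fitting, and
multi-echo combination are out of scope: the package scores and renders
volumes that are already gridded together.

Everything is testable without external data because a synthetic phantom
module generates EPI/anatomical volumes with a machine-readable record of
every injected artifact.

# Data model

Images are carried by S4 classes — `Dataset4D` (values indexed x, y, z, t;
voxel sizes in mm; TR in seconds; a 4x4 affine mapping 0-based indices to
world mm; per-run volume counts), `Dataset3D`, and `Mask3D`. Text carriers
are `Matrix1D` (whitespace-separated numeric matrices with `#` comments) and
`ReviewDict` (ordered label-to-value pairs, serialized either as
`label : value` lines or as a flat JSON object). Numeric review values are
written with up to six significant digits, the precision such files
conventionally print; the two dialects of one dictionary therefore compare
equal after a round trip.

# Motion, outliers, and censoring

The motion magnitude is the Euclidean norm of the forward differences of the
six rigid-body parameters (3 rotations in degrees, 3 translations in mm),
reset to zero at the first volume of each run. Degrees and millimetres enter
unscaled; for a sphere of roughly 57 mm radius one degree of rotation moves
the surface about one millimetre, which is the usual justification for
mixing the units, and we document rather than rescale it.

The outlier fraction needs a concrete voxelwise rule. Ours: detrend each
in-mask voxel per run with Legendre polynomials of order
`1 + floor(run_seconds / 150)`; call a residual an outlier when its
magnitude exceeds `qnorm(1 - 0.001 / (2 T)) * 1.4826 * median(|residual|)`
with `T` the run length. The threshold adapts to run length (a Bonferroni-style
guard at about one false flag per 1000 series) and the MAD scale is robust to
the spikes being sought. On a clean Gaussian phantom the expected flagged
fraction is below 1e-4 per volume, which is what makes the zero-false-positive
contracts of the detectors attainable.

Censoring removes volume `t` when its enorm exceeds 0.3 mm-equivalent or its
outlier fraction exceeds 0.05 (both configurable). Because a forward
difference implicates both members of the pair, the volume preceding a
suprathreshold enorm is censored too by default (`extend_previous`); this is
exposed as a flag since conventions differ. Summary statistics are reported
both before (BC) and after (AC) censoring with type-7 quantiles; a fully
censored series leaves AC flagged undefined rather than erroring.
`selectMinOutlierVolume` can skip a configurable number of initial volumes —
its `censorable_prefix` argument — so a pre-steady-state prefix cannot be
chosen as the registration base.

# Correlation summaries

GCOR is computed by the unit-norm identity: demean and scale each in-mask
series to unit norm, average those vectors, and take the squared norm. That
equals the mean of the full voxel-pair correlation matrix (self-pairs
included) at O(NT) cost; the O(N^2) definition is kept as the test oracle.
`corr_brain` correlates every voxel with the mean in-mask residual series
and carries its display convention (transparent below |r| = 0.3, range 0.6)
as metadata. Radial correlation correlates each voxel with a
Gaussian-weighted neighborhood average (FWHM 20 mm by default), computed by
smoothing each volume restricted to the mask and renormalizing by the
smoothed mask, so edge voxels are not diluted by the background; the center
voxel is included in its own average, and the map tends to 1 as the FWHM
shrinks below a voxel. Seed maps snap out-of-mask seeds to the nearest
in-mask voxel with a warning; a toy three-network seed table (default-mode,
visual, auditory labels, placed in opposite hemispheres) mirrors the usual
resting-state presentation on the phantom.

# TSNR and the ROI table

TSNR is mean(signal)/sd(noise) per voxel with stage-dependent inputs: after
volume registration the noise is the detrended series (`detrendDataset`),
after regression it is the residual series. Zero-sd voxels get value 0, and
"zero-valued" in the ROI table means exactly 0 — such voxels mark masked-out
or failed fits, not small values. ROI depth (`Dvox`) uses face connectivity
with boundary depth 1 and equals the number of successive face-erosions that
empty the region (the test oracle); ties in the deepest voxel resolve to the
earliest index order, and the location is reported in mm.

The per-metric warning thresholds are heuristics (the direction of each
warning is principled, the cutoffs are local conventions, all overridable):
`nvox` below 20/10/5 for mild/medium/severe, `nzer/nvox` above 0.1/0.25/0.5,
`dvox` below 3/2, `t75` below 50/30/15, and the quartile slope
`(t75 - t25)/tmed` above 0.75/1.0/1.5 (a zero median is graded severe
outright). Warn levels are monotone in each metric by construction.

# Degrees of freedom

The DF ledger is `total = censored + regressors + left`. The bandpass cost
enumerates DFT frequencies `k/(T tr)` for `k = 1..floor(T/2)`: each removed
frequency costs two DFs (sine and cosine) except the Nyquist bin for even
`T`, which costs one; DC belongs to the drift regressors. Band endpoints are
inclusive — the convention matters at desk precision: retaining 0.01–0.1 Hz
costs 62.5% of DFs for a 200-volume TR 2 s run and 80.5% at TR 1 s, i.e.
"almost 60%" and "nearly 80%"; exact counts brush those round figures from
either side depending on `T` (79.0% at `T = 100`, TR 1 s), so our tests
assert floors one point beneath them.

Ideal stimulus responses are boxcars convolved with a unit-peak kernel — a
gamma variate `(t/p)^4 exp(4 - 4t/p)` peaking at `p = 4.5` s, the boxcar
itself for block designs, or an identity pulse for checks — sampled on the
TR grid (the sampled maximum can fall slightly below 1 between grid
points). Per-stimulus censor fractions count censored volumes among the
nonzero-response volumes and are reported at 3 decimals. Collinearity
warnings grade |r| at 0.4/0.6/0.9; a duplicated timing file shows up as a
severe |r| = 1 pair, and constant columns are flagged separately.

# Artifact detectors

**Left-right flips.** The local Pearson correlation (LPC) cost partitions
the mask into non-overlapping cubes of edge `2r + 1` (default 5), computes
the intensity correlation per block with at least 8 in-mask voxels, and
averages `-sign(r) r^2` with block-size weights: bounded in [-1, 1], lower is
better. The flip check compares the cost as-is against the cost with the EPI
mirrored across its left-right axis (identified from the affine's dominant
world-x direction); a relative margin of 2% is required before declaring
`DO_FLIP` or `NO_FLIP`, otherwise `UNDECIDED` — a perfectly symmetric volume
ties exactly. `DO_FLIP` is a severe warning.

**Variance lines.** After the standard detrend, each in-plane column (i, j)
with at least half its slices in the mask is scored by the median temporal
sd over its in-mask slices; columns above 2.5x the median column score are
flagged and face-adjacent flags merge into line clusters, reported with both
index and mm peak coordinates. Any cluster is a medium warning; three or
more clusters, or a score ratio above 5, is severe. The column-median
statistic and its factor are explicit local conventions — the artifact is
defined by pictures in the field, not by a formula — and both are
configurable.

**Pre-steady state.** Initial consecutive volumes whose in-mask mean exceeds
1.05x the run's 10%-trimmed mean of volume means are counted per run
(trimming keeps the artifact from inflating its own baseline; the rule is
prefix-only by design). Any nonzero count is a medium warning.

Warning levels form the total order none < undecided < mild < medium <
severe with fixed display colors; the report's "warns" menu label takes the
maximum level's color.

# The synthetic phantom

The generator is the package's study condition, not a tuning knob. The
default subject is a 32 x 32 x 20 grid of 2.5 mm voxels, TR 2 s, 200
volumes in one run: an ellipsoidal three-tissue anatomical with a seeded
intensity texture and a deliberate single-hemisphere lobe (so mirroring is
detectable), an EPI whose baseline is the anatomical rescaled to mean 1000
inside the mask with Gaussian noise sd 10 (whole-brain TSNR about 100),
quadratic drift of amplitude 10, one 1 mm motion spike, one variance line at
scale 5, and one seeded network (radius 3 voxels, amplitude twice the noise
sd, giving in-mask correlations near 0.9). Motion spikes perturb the EPI as
a one-voxel shift plus a 5% intensity change rather than a full rigid
resample — subpixel realism would buy nothing here, while integer shifts
keep the ground truth exact. Pre-steady-state volumes multiply the first
`presteady_n` volumes by 1.15: detectable, not extreme.

The `TruthRecord` lists the expected censored volumes analytically from the
spec (a spike of magnitude above the limit at `t` censors `t-1`, `t`,
`t+1` within its run; volumes carrying an intensity perturbation censor
`t`), never by running the detectors, so the recovery tests compare two
independent routes. Generation is a pure function of (spec, seed).

What the phantom does *not* emulate: k-space physics, B0 distortion,
physiological noise spectra, spatial autocorrelation of thermal noise, and
realistic anatomy. Passing the recovery suites therefore demonstrates that
the detectors implement their stated rules and recover their stated targets
at the stated magnitudes — not that those magnitudes correspond to any
particular scanner's artifact severity.

Detector validation isolates artifact classes: the network-recovery phantom,
for instance, disables motion spikes, because an uncensored 5% whole-volume
intensity change legitimately suppresses raw-series seed correlations — on
real data those volumes would be censored or regressed before seed maps are
read. The interaction is a property of the data, not a defect of either
detector, and mixing them in one recovery assertion would test neither
cleanly.

# Report and group tables

The report is a self-contained directory — `index.html` plus `media/` PNGs
and two JSON files — with ten fixed blocks in order: `vorig`, `ve2a`,
`va2t`, `vstat`, `mot`, `mecho`, `regr`, `radcor`, `warns`, `qsumm`. Each
block is an anchor usable as a jump target; missing optional inputs leave a
placeholder note rather than a broken link (the multi-echo block is always a
placeholder in this package), and no absolute paths appear, so the
directory can be moved or shared. Montage slices are chosen inside a light
automask (voxels above 25% of the 98th-percentile intensity — a concrete
stand-in for "light automasking", configurable) and labeled in mm.
Statistical overlays use percentile rules (colorbar max at the 99th, the
threshold at the 90th in-mask percentile for omnibus F; two-sided p = 0.001
t quantiles when a DF is known) with quadratic alpha fade below threshold,
outlined suprathreshold clusters, and no brain masking of the overlay. The
grayplot Z-scores each series, clips at the two-sided p = 0.001 normal
quantile (3.2905) so plots compare across subjects, and orders voxels by an
angular embedding of their correlations with the two leading principal
components, cut at the widest angular gap — co-fluctuating clusters end up
as contiguous bands.

Ratings are good (+), bad (X), other (?); commenting on an unrated block
automatically applies "other". Because the interactive buttons of a
server-backed report are out of scope, ratings are applied through
`rateBlock()` (or the `fmriqc rate` CLI) writing the same JSON schema, and
the FINAL rating is merged into the subject's review JSON so group
filtering can use `'FINAL rating' EQ bad`.

Group tables keep the union of review keys in first-seen order, expand
list-valued entries into suffixed columns on write (TSV by default, CSV on
request — "spreadsheet" output is tab-separated here since that dialect is
unambiguous), and never drop a missing cell silently. Filtering supports
VARY / EQ / GT / LT / GE / LE plus SHOW columns; VARY compares strings
exactly and numbers at 1e-9 relative tolerance (values round-trip through
text), multi-valued cells trigger if any element does, and a type mismatch
(an order comparison against a string) is an error rather than a silent
FALSE. Outliers and keepers partition the subject set exactly. The
`gtkydScan` header scan records dims, voxel sizes, TR, volume count,
orientation, datum kind and value range per file (a 4095 maximum surfaces
12-bit saturation), then reports any property that varies across the
collection.

# Numerical choices and problem sizes

Quantiles are type 7 throughout, for determinism. Correlations of
zero-variance series are defined as 0 and flagged or excluded per operation.
Ties in argmax selections resolve to the earliest index. The test and
validation suites run the default phantom where stage timing matters and
scale down to 6–16 voxel grids for brute-force oracles (per-voxel loops,
explicit correlation matrices, erosion counts); injection-recovery suites
use 20 seeds per detector at 24–32 voxel grids and 10–100 volumes, sizes at
which every contract above is exercised in seconds. The full default-phantom
pipeline (generation through report) completes in a few seconds on one CPU.

# Known limitations

The outlier rule, the variance-line statistic, the warn-level cutoffs, and
the automask recipe are explicit local conventions standing in for behavior
that the surrounding literature specifies only directionally; all are
configurable and documented above. The flip margin (2%) trades sensitivity
for noise immunity and has only been calibrated on phantoms. The `mecho`
block is a placeholder. BRIK/HEAD, DICOM and surface formats are not read;
blur estimation (ACF) is not implemented and its review key is reported only
if supplied by the caller.
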