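---
title: "Quantitative amino-acid PET analysis for IDH-mutant glioma: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative amino-acid PET analysis for IDH-mutant glioma: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetquant)
```

## The measurement model

[¹⁸F]FET is an amino-acid tracer taken up by glioma cells through L-type
amino-acid transporters. Static analysis of an FET scan reduces a
standardized-uptake-value (SUV) volume to a handful of biomarkers that are
all referenced to healthy tissue:

* the **background mean** `SUV_bg`, the mean SUV in a region of the healthy
  contralateral hemisphere;
* the **PET volume**, the set of voxels with `SUV >= 1.6 x SUV_bg` (the
  conventional segmentation threshold for FET);
* **TBR_max = SUV_max / SUV_bg** and **TBR_mean = SUV_mean / SUV_bg**, with
  `SUV_max`/`SUV_mean` taken inside the PET volume;
* **PET positivity** in the PET-RANO sense: `TBR_max >= 1.6`, boundary
  included.

Because every quantity is a ratio against `SUV_bg`, the whole metric set is
invariant under global rescaling of the volume — a property the test suite
asserts rather than assumes.

`fetquant` deliberately consumes *pre-registered* inputs: PET volumes, MRI
lesion masks (FLAIR hyperintensity, contrast enhancement) and the background
ROI must share one voxel grid, and a grid mismatch is a hard error rather
than a silent resample, because resampling a mask changes voxel counts and
therefore Dice and TBR values. An externally estimated rigid/affine
transform can be applied explicitly (`apply_affine_resample()`,
nearest-neighbour, binary-preserving), but registration itself is out of
scope.

Negative SUVs, which arise from reconstruction noise, are clamped to zero at
load time with a reported count rather than rejected.

## Background ROI and segmentation

The background ROI is a required input mask. Published FET protocols place
it in the healthy contralateral hemisphere but do not fix its geometry, so
the package refuses to invent anatomy: the only helper provided,
`mirrored_background_roi()`, reflects a user-given centre across the
mid-sagittal plane and draws an ellipsoid there. A configurable minimum ROI
size (default 100 voxels) guards against unstable background means.

Segmentation thresholds the volume at `threshold_factor x SUV_bg`
(default 1.6) and then cleans up connected components: components smaller
than `min_component_ml` (default 0.1 ml, 26-connectivity) are discarded as
noise, and an optional seed point keeps only the component containing — or,
when the seed voxel itself is sub-threshold, nearest to — the seed. The seed
mechanism is a reproducible stand-in for the operator's "semiautomatic"
lesion selection; with neither seed nor size filter the segmentation is
exactly the per-voxel threshold scan, which is how the oracle tests check
it. An empty mask is a valid result (a PET-negative tumour), not an error.

For PET-negative cases the uptake report still carries a `TBR_max`, computed
from the global maximum within a user-supplied search region (or the whole
volume). This choice mirrors the fact that clinical series report TBR_max
values down to 1.0 for negative tumours, which is only possible if the
measurement does not require a segmented lesion. Whether such values should
come from a fixed search VOI or the whole brain is not settled; the package
exposes `search_mask` and defaults to the whole volume.

## Dice overlap and evaluability

Spatial PET–MRI agreement uses the Dice coefficient
`2|A ∩ B| / (|A| + |B|)` on voxel counts (identical grids are enforced
upstream, so counts and millilitres are proportional). The evaluability rule
is strict: if either mask is empty — no visible uptake, or no segmentable
MRI lesion — the comparison is *not evaluable* and excluded, never scored 0
or 1. The panel function reports PET–FLAIR and PET–CE separately, with an
absent CE mask producing a not-evaluable CE result.

## Dynamic analysis

Dynamic acquisitions (0–40 min post-injection) are reduced to time–activity
curves (TACs). The kinetic ROI is a 90% isocontour on the 10–30 min
summation image, applied volumetrically (the per-slice alternative is not
used; the volumetric reading keeps the ROI definition independent of slice
coverage). The same ROI is applied to every frame; the TAC is the per-frame
ROI mean SUV against frame mid-times.

The acquisition frame schedule is a required input because published
protocols rarely state their binning. The package default is
(0–5, 5–10, 10–15, 15–20, 20–30, 30–40) min, chosen so that the achievable
time-to-peak values are exactly {2.5, 7.5, 12.5, 17.5, 25, 35} min — the
levels at which clinical TTP_min analyses report their results (12.5 min
early peaks; 17.5–35 min late peaks).

### Classification rule

The field describes three qualitative TAC patterns: *increasing*
(continuous rise, or rise then plateau), *decreasing* (initial peak then
constant decline), and *stable* (fluctuation within ±10% of the peak). A
reproducible pipeline needs a deterministic operationalization. With peak
index `p` (earliest global maximum, value `s_p`), early uptake `s_early`
(mean over frames with mid-time ≤ 5 min), relative rise
`R = (s_p − s_early)/s_p` and relative late change `Δ = (s_last − s_p)/s_p`:

1. **increasing** iff `R > 0.10` and `Δ ≥ −0.10` — a genuine rise whose
   level is maintained to the end. For a curve peaking at the final frame
   `Δ = 0`, so true continuous rises always qualify.
2. **decreasing** iff `Δ < −0.10` and the post-peak values are
   non-increasing within a per-step tolerance of `0.10 × s_p`.
3. **stable** iff neither fired and all values lie within `±0.10 × s_p` of
   the peak.
4. otherwise the sign of the least-squares slope over the late window
   (mid-times > 5 min) decides.

All four thresholds are configurable (`kinetic_config()`). One design point
deserves emphasis: a peak at the final frame is *not* by itself sufficient
for the increasing class. Under measurement noise the argmax of a genuinely
flat curve lands on the last frame about one time in six, and a rule that
treats "peak at end" as increasing therefore misclassifies a large fraction
of stable tumours; simulation at 2% relative noise showed stable-class
recovery capped near 86–97% under that rule across a wide range of stable
curve shapes. Conditioning the increasing class on an actual rise
(`R > 0.10`) removes this failure mode (stable recovery ≈ 99.6% in a
30 000-replicate simulation) and matches the qualitative definition — a
curve that merely fluctuates inside the stability band never "continuously
increased".

Ties at the maximum break to the earliest frame, following the "initial
peak" reading; this also makes TTP deterministic.

### TTP and TTP_min

TTP is the mid-time of the earliest frame attaining the curve maximum.
TTP_min is evaluated across axial tumour slices: each slice with at least
`min_slice_voxels` ROI voxels (default 3; smaller cross-sections are
noise-dominated and are skipped with a logged count) contributes a slice
TAC, and TTP_min is the smallest TTP value occurring in at least two
*adjacent* slices with exactly equal TTP. The adjacency-with-equality
reading is the most literal one; since it can fail to produce a value (no
repeated TTP anywhere), the implementation falls back to the whole-ROI TTP
and flags the fallback. The tumour-level kinetic class is decreasing if the
whole-ROI curve is decreasing *or* at least two adjacent slices are
decreasing (the heterogeneous pattern); otherwise the whole-ROI class
stands.

## Cohort statistics

The statistics layer reproduces a clinical results-table workflow: metric
variables as median (range), categorical variables as n (%), and the
standard test battery — Pearson chi-square *without* continuity correction
(required to reproduce published chi-square statistics from their printed
contingency tables, including 2×2 tables), Fisher's exact test, the
Mann–Whitney U test, the Kruskal–Wallis test, and Cohen's κ for reader
agreement. All p-values are two-tailed; no multiplicity correction is
applied anywhere, matching the hypothesis-generating framing such studies
use. Missing values (no dynamic scan, no CE lesion, PET-negative) are
excluded per analysis with the exclusion counts reported, so every analysis
carries its own denominator.

The Mann–Whitney U is reported in the `min(U_x, U_y)` convention with
midrank tie handling. For combined samples up to 25 the two-sided p-value
is the exact permutation probability, computed by a counting dynamic
programme over doubled midranks (exact also in the presence of ties); above
that, a normal approximation with tie correction and continuity correction
is used. The exact path is verified in the test suite against exhaustive
`combn` enumeration, which is kept independent of the implementation.

## Synthetic data: what it emulates, and what it does not

No imaging data accompanies the published cohorts this pipeline targets, so
validation rests on synthetic ground truth:

* **Static phantoms** — homogeneous Gaussian background (default mean 1.0,
  sd 0.05) with hard-edged ellipsoidal lesions at a specified TBR. Hard
  edges are a deliberate anti-realism: ground truth must be unambiguous for
  oracle equality (noiseless phantoms make segmentation exactly
  invertible).
* **Dynamic phantoms / TACs** — three curve families on the default
  schedule: a saturating exponential rise (increasing), a linear rise to a
  nominal peak followed by a ≥15% linear decline (decreasing; 25% by
  default), and a flat curve within 1% of its unique peak frame (stable).
  Noise is independent Gaussian per voxel and frame, relative to the lesion
  peak.
* **Mask pairs** — given a reference mask A and a target Dice d, the
  companion keeps the `round(d·|A|)` voxels of A nearest its centroid and
  adds outside voxels nearest the centroid until `|B| = |A|`, giving
  `Dice = round(d·|A|)/|A|`, within `1/(2|A|)` of the target — well inside
  the ±0.02 contract for any lesion of ≥ 25 voxels.
* **Cohorts** — stratified by histology × WHO grade with per-stratum
  frequencies of contrast enhancement, PET positivity, dynamic
  availability, kinetic class and TTP_min level, plus log-normal TBR and
  near-target Dice draws. The default exact-count mode converts
  `frequency × n` to integers by largest-remainder rounding, so marginal
  tables are reproduced deterministically — this is what lets a generated
  cohort reproduce published chi-square statistics exactly.

The default cohort specification (`glioma_cohort_spec()`) emulates a
147-patient IDH-mutant glioma series (79 astrocytomas across WHO grades
2/3/4, 68 oligodendrogliomas across grades 2/3) including its published
positivity rates and kinetic-class margins. Two quantities in that
specification are under-determined by published margins and were completed
once, as plausible defaults: the joint histology × grade × class split
(any completion consistent with both margins reproduces the published
chi-squares), and the per-grade positivity split within astrocytomas (only
the overall 35/79 is constrained).

What the generators do **not** emulate: PET physics (scatter, attenuation,
point-spread, partial volume), anatomical background structure, correlated
noise, irregular lesion shapes, and MRI contrast mechanisms. Passing the
synthetic suite therefore demonstrates that the *computational* pipeline is
correct and self-consistent, not that the thresholds generalize to scanner
data; threshold choices (1.6, 90%, ±10%) are conventions taken from the
field, not re-derived here.

## Numerical choices and degenerate inputs

* Summation windows must coincide with frame boundaries; partial-frame
  interpolation is refused.
* The isocontour ROI is non-empty by construction (the maximum voxel always
  qualifies); an all-zero summation image is an error.
* Connected-component labelling uses vectorised minimum-label propagation
  over 6/18/26-neighbourhoods, implemented in R; grids in this pipeline are
  small enough that this is never the bottleneck.
* An all-tied Kruskal–Wallis input returns `H = 0, p = 1` rather than NaN.
* Empty-vs-empty mask comparisons are not evaluable rather than Dice 0
  or 1.
* All generators are bit-deterministic under their seeds; the pipeline
  itself is deterministic, so identical config + inputs give identical
  reports (asserted byte-for-byte on CSV outputs in the tests).

## Problem sizes used in the shipped checks

The test-suite and acceptance-script problem sizes are chosen to exercise
every code path at desk scale: 50 random phantoms on grids up to ~32³ for
segmentation-oracle equality (at factors 1.2/1.6/2.0), 1000 random mask
pairs for the Dice property suite, 200 noisy + 50 noiseless TACs per
kinetic family, 2000 null replicates for the Kruskal–Wallis level check,
and a 30-patient noiseless end-to-end cohort on 24×24×12 grids. These sizes
give tight Monte-Carlo bounds (e.g. a ±2% band on the type-I error at
n = 2000) while keeping a full run in minutes.

## Known limitations

* Multifocal lesions are all retained by default (or reduced to one
  component by the seed mechanism); published series do not state whether
  multifocal PET volumes were merged or measured per focus.
* TTP_min's adjacency rule requires exactly equal TTPs; a
  one-frame-tolerance variant would be a one-line change
  (`min_consecutive_slices` and the equality predicate are localized in
  `ttp_min()`), but the literal reading was kept.
* The empty-segmentation TBR_max search region defaults to the whole
  volume, which on real scans would include scalp and venous sinuses; on
  phantoms this is immaterial, on clinical data a search mask should be
  supplied.
* Partial-volume correction, kinetic modelling with input functions, and
  survival endpoints are out of scope.
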