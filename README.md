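# fetquant

Quantitative [¹⁸F]FET PET/MRI analysis for IDH-mutant glioma, as an R
package. `fetquant` implements the standard static and dynamic amino-acid
PET evaluation used in neuro-oncology imaging — background-referenced
tumour segmentation, TBR metrics and PET-RANO positivity, PET–MRI Dice
overlap, time–activity-curve (TAC) kinetics with minimal time-to-peak
(TTP_min) — together with the cohort statistics layer that clinical series
report, and synthetic phantom/cohort generators with known ground truth so
the whole pipeline is testable without any patient data.

It is written for imaging scientists who want a reproducible, scriptable
version of what is usually done interactively on a vendor workstation.

## The quantities

With `SUV_bg` the mean standardized uptake value in a healthy contralateral
background ROI:

* **PET volume** — voxels with `SUV ≥ 1.6 × SUV_bg` (threshold factor
  configurable), after removal of sub-0.1 ml components and optional
  seed-point component selection;
* **TBR_max / TBR_mean** — `SUV_max / SUV_bg` and `SUV_mean / SUV_bg`
  inside the PET volume; **PET-positive** iff `TBR_max ≥ 1.6` (PET-RANO,
  closed boundary);
* **Dice** — `2|V_PET ∩ V_MRI| / (|V_PET| + |V_MRI|)` against FLAIR and
  contrast-enhancement masks, computed only when both lesions are
  segmentable;
* **TAC class** — increasing / stable / decreasing from a deterministic
  operationalization of the standard qualitative definitions (±10%
  stability band around the peak);
* **TTP_min** — shortest time-to-peak occurring in at least two adjacent
  axial tumour slices, from a 90% isocontour ROI on the 10–30 min summation
  image applied to every frame.

Inputs are NIfTI volumes and masks on a common grid (pre-registered; grid
mismatches are hard errors), a frame schedule as JSON/YAML for dynamic
series, and per-patient CSV records for the cohort layer.

## Worked example

Everything below runs on synthetic phantoms with known ground truth:

```r
library(fetquant)

ph  <- make_static_phantom(phantom_spec(seed = 42))   # noisy bg + TBR-2.5 lesion
bg  <- estimate_background(ph$volume, ph$background_mask)
seg <- segment_lesion(ph$volume, bg)
compute_uptake_metrics(ph$volume, seg$mask, bg)
#> <uptake_metrics> TBR_max 2.498, TBR_mean 2.498, PET volume 2.06 ml, PET-positive

flair <- make_mask_pair(ph$lesion_mask, 0.55, seed = 42)  # MRI mask at target Dice
dice_coefficient(seg$mask, flair)
#> <dice_result> Dice 0.549 (|A| 2.06 ml, |B| 2.06 ml, A^B 1.13 ml)

dp  <- make_dynamic_phantom(phantom_spec(seed = 42),
                            dynamic_spec(curve_family = "decreasing",
                                         peak_time_min = 12.5, seed = 42))
roi <- isocontour_roi(summation_image(dp$series, 10, 30), 0.9)
classify_tumour_kinetics(extract_slice_tacs(dp$series, roi),
                         extract_tac(dp$series, roi))
#> <kinetic_result> class decreasing (whole-ROI decreasing), TTP_min 12.5 min
```

The background estimate recovers the generator mean (1.001 over 257 ROI
voxels), segmentation at 1.6 × background finds exactly the ground-truth
lesion (2.06 ml), the companion MRI mask lands on its 0.55 Dice target, and
the decreasing-family dynamic phantom is classified decreasing with its
nominal 12.5 min peak recovered.

Cohort level, on a generated 147-patient series carrying published
stratified frequencies:

```r
rec <- make_cohort(glioma_cohort_spec(seed = 42))
cohort_analysis(rec)
#> <cohort_result> 147 patients (97 PET-positive, 91 with dynamic data), 0 failure(s)
#>   kinetics_by_grade : <test> chi2 = 17.62, df = 4, p = 0.001464
#>   kinetics_by_histology : <test> chi2 = 2.967, df = 2, p = 0.2268
#>   ...
```

The kinetic-pattern × WHO-grade chi-square (17.6) and the histology ×
kinetic-pattern chi-square (3.0) are recomputed from the generated records,
not stored.

A thin CLI over the same functions lives at `inst/cli/fetquant`
(subcommands `static`, `dynamic`, `dice`, `cohort`, `run`, `simulate`).

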