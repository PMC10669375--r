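---
title: "Adaptive cyst segmentation for LAM chest CT: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive cyst segmentation for LAM chest CT: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Lymphangioleiomyomatosis (LAM) progressively replaces lung parenchyma with
air-filled cysts.  The standard imaging biomarker is the *cyst score*: the
fraction of the total lung volume occupied by cysts on chest HRCT.  Patients
are followed for decades, across scanner generations, reconstruction kernels
and physiological states, and three kinds of variability defeat any fixed
radiodensity threshold:

1. **Air calibration.** The external air background, nominally -1000 HU,
   drifts between roughly -954 and -1018 HU from series to series.
2. **Superior-inferior airway drift.** The radiodensity of air inside the
   trachea and main bronchi varies with axial position, most strongly in the
   apical chest, and cyst air follows it.
3. **Parenchymal density.** Mean non-cystic parenchyma differs by over
   100 HU between patients and can vary within one section (e.g. positional
   atelectasis elevating the anterior lung), so a threshold tuned for one
   region under-segments another.

`lamcyst` implements a fully automated pipeline that derives *local*
thresholds from the image itself.

## The model

Let $I(x,y,z)$ be the harmonized radiodensity volume.  The pipeline
estimates:

* $I_\mathrm{background}$ — the external air level, the first substantial
  peak of the whole-volume histogram scanned upward from -1024 HU;
* $I_\mathrm{airway}(z)$ — per-slice mean radiodensity inside the segmented
  trachea/main bronchi, with the most inferior measured value copied to all
  slices below (and, as a totalizing extension, the most superior value
  copied above and interior gaps interpolated);
* $I_\mathrm{air}(z) = \tfrac12\!\left(I_\mathrm{airway}(z) +
  I_\mathrm{background}\right)$ — the reference radiodensity of intra-lung
  air at slice $z$;
* $I_p(x,y,z)$ — the local non-cystic parenchyma level: the dominant mode of
  a Gaussian-weighted histogram of the radiodensities inside a 35-mm
  circular in-plane window centred at the voxel, restricted to the band
  $[\,I_\mathrm{air}(z)+25,\ -500\,]$ HU (which excludes large air voids
  below and vessels above), accumulated in 1-HU bins and smoothed with a
  1-D Gaussian before taking the argmax.

A lung voxel (airways excluded) is cystic when

$$I < \frac{I_p + I_\mathrm{air}(z)}{2} \quad\text{where } I_p
\text{ exists},\qquad I < I_\mathrm{air}(z) + 25 \text{ HU otherwise,}$$

the fallback covering window-sized air voids (centres of very large cysts)
where the mode filter is undefined.  The cyst score is the cystic voxel
volume divided by the lung volume; airways are excluded from numerator and
denominator alike.

The attraction of the *mode* (rather than a mean or median) is robustness:
small changes in the band limits move histogram mass at the edges but not
the peak, which the package verifies directly (shifting the lower limit by
±10 HU changes $I_p$ at well under 1 % of voxels).

## Pipeline stages and their tunables

All parameters live in one YAML-backed configuration (`default_config()`);
the values below are the defaults.

| Stage | Parameter | Default | Why |
|---|---|---|---|
| Harmonization | per-kernel Gaussian width (mm, sd) | table; unknown kernel → 0 | kernel-dependent resolution/noise; widths are site data to be calibrated per fleet |
| Lung segmentation | air threshold | -320 HU | conventional midpoint between aerated lung and soft tissue |
|  | closing radius | 3 vox | smooths the pleural boundary, keeps vessels/cyst walls inside |
| Trachea search | superior slice fraction | 15 % | trachea, not bronchi, should dominate the search region |
|  | area gate | 20–500 mm² | adult tracheal cross-sections |
|  | circularity gate | ≥ 0.4 of bounding circle | rejects elongated pleural air |
| Airway growing | threshold | seed mean + 150 HU (≤ lung threshold) | follows lumen while rejecting parenchyma |
|  | leak rule | area > 3 × median of previous 10 slices | stops growth where the tree opens into a large air space |
| Vessel exclusion | threshold | > -500 HU | doubles as the histogram band's upper limit |
| Background peak | count ≥ 1 % of voxels, prominence ≥ 20 % of height | — | "substantial" made quantitative |
| Mode filter | window 35 mm, Gaussian sd 8.75 mm truncated at the rim | — | window per the method; the sd makes the stated centre-weighted profile concrete |
|  | histogram smoothing sd | 10 HU | suppresses noise modes at typical harmonized HRCT noise |
|  | availability gate | in-band weight ≥ 5 % of window weight | quantitative form of "no result at large voids" |
|  | evaluation stride | 4 px, bilinear interpolation | pure acceleration; stride 1 recovers the exhaustive map (agreement ≤ 5 HU at > 99 % of voxels) |

Numerical conventions that prevent silent bugs:

* **Width convention.** Kernel-harmonization widths are Gaussian *standard
  deviations* in mm, not FWHM.  The 0.529-mm target resolution is metadata;
  the grid is never resampled, and kernels already softer than the target
  use width 0 (no deconvolution).  Filtering is in-plane only, since the
  harmonization target is in-plane resolution.
* **Bin anchoring.** Local histograms are binned relative to the band's
  lower limit and the background histogram uses integer-centred bins
  extending below the -1024 HU scan start.  Consequently an integer global
  HU offset shifts every estimate by exactly that offset and leaves the
  adaptive cyst mask bitwise unchanged — the formal version of robustness
  to calibration drift.
* **Ties.** The smoothed-histogram argmax breaks ties toward the lower HU,
  which lowers the local threshold, i.e. errs toward calling fewer voxels
  cystic.
* **Padding.** Voxels at or below -1500 HU are treated as field-of-view
  padding and excluded from every histogram and filter support.  The cutoff
  is below -1024 so that the noise tail of a miscalibrated air background
  (observed down to -1018 HU) is never truncated, which would bias the
  background peak.
* **Background sub-bin refinement** uses the count centroid over the peak's
  half-height run; a fixed narrow centroid window would inherit the Poisson
  jitter of the argmax when the air peak is many bins wide.
* **Airway growing connectivity.** Slices are accepted by direct overlap
  with the slice above (8-connected in plane).  Diagonal-only (26-connected)
  adjacency was rejected: where the tree runs obliquely it lets growth jump
  across the ~1.5-mm airway wall into lung air, and the leak rule then
  truncates the tree at the carina.  Direct overlap tracks any tube whose
  consecutive cross-sections overlap, always true at main-bronchus scale.
* **Degenerate inputs.** Missing trachea, absent lungs, or a cropped field
  of view without an air peak raise stage-named errors rather than
  propagating nonsense; series shorter than 3 exams yield zero
  inconsistency measures rather than an error.

## Longitudinal metrics

The *longitudinal inconsistency* of three consecutive cyst scores is the
residual standard error of the straight line through them:
$\sqrt{\mathrm{SSR}/(n-2)} = \sqrt{\mathrm{SSR}}$ for $n = 3$.  This
"residual" reading is adopted (rather than the standard error of the slope)
because the quantity is meant to represent the deviations of the three
points from the short line through them; both are computable but only the
residual form has cyst-score units and the reported magnitude (~0.01).
A patient with $n$ exams yields $n-2$ measures; the per-patient maximum is
the worst inconsistency.  Times are calendar years from the first exam, not
exam indices.  Cyst scores are correlated with same-visit pulmonary
function results (FEV1, FEV1/FVC, DLco, % predicted) by squared Pearson
correlation; the visit-matching window is configurable and defaults to the
same day.  Contrast enhancement is carried as metadata but unused by the
algorithm, which has no published handling for it.

## The phantom: what it emulates, and what it does not

`make_phantom()` builds a deterministic synthetic chest: a soft-tissue
elliptical body (+40 HU) in external air, two lung ellipsoids of uniform
parenchyma with an optional anterior–posterior ramp, a trachea splitting
into two sealed main bronchi carrying a linear superior–inferior
radiodensity profile, thin intrapulmonary vessels, and spherical cysts
whose air value tracks the airway profile at their slice — the coupling
that makes airway-anchored thresholds the right reference.  Additive
Gaussian noise is seeded and reproducible.

Default conditions (chosen once, as the package's study conditions):
background -994 HU (the documented cohort mean), parenchyma -880 HU,
airway drift from background+28 HU apically to background+8 HU inferiorly,
noise sd 10 HU (a typical harmonized-series level; the atelectasis scenario
uses 20 HU), grid 128×128×80 at 1×1×2 mm for fast tests.  Cysts are
rendered with partial volume — voxel values mix air and parenchyma by
sub-voxel occupancy, truth membership at occupancy ≥ ½ — because the mixed
shell around small cysts is exactly what fixed global thresholds truncate
in elevated-density regions; without it the under-segmentation phenomenon
cannot be reproduced.  The random-spec generator spans background
-1018…-954 HU and parenchyma up to -750 HU, but enforces a minimum
air–parenchyma contrast of 80 HU: below that, cysts are radiologically
undefined for any density-based method and the histogram band cannot
contain the parenchyma peak.

The phantom does **not** emulate: realistic airway trees beyond the main
bronchi, ribs or mediastinal anatomy, beam hardening, scanner-specific
noise texture or resolution anisotropy, respiratory motion, or contrast
enhancement.  Passing the phantom suite therefore demonstrates the
*algorithmic* properties (calibration invariance, regional adaptivity,
recovery of known truth under stated noise) — not clinical performance,
which requires patient data.

## Validation suite and problem sizes

The test suite regenerates every fixture from code: DICOM and NIfTI round
trips (cross-checked against an independent reader), analytic oracles for
the Gaussian filter, brute-force oracles for the weighted-histogram mode
and for the regression metric, and property tests for offset equivariance,
atelectasis robustness, leak control and mode stability.  Phantom-based
checks run at the 128×128×80 preset (whole-pipeline checks), 96×96×40
(stride-equivalence and stability maps) and 64×64×24 (fast unit tests);
`scripts/acceptance.R` re-runs the full set of headline quantities from
scratch at those sizes.

## Known limitations

* The per-kernel width table ships with illustrative entries only; real use
  requires calibrating widths for the local scanner fleet.
* Airway segmentation stops at main-bronchus scale by design; peripheral
  airways are counted as lung and can contribute sub-voxel air volume.
* The cyst score uses lung volume exclusive of the large-airway lumen; a
  convention including it would differ by roughly the airway volume
  fraction (~1–2 %).
* No per-cyst instance statistics (size distributions, spatial clustering)
  are computed, though the cyst mask supports them downstream.
* The significance tests comparing methods in the source study are not
  reimplemented; the package computes the quantities, not the hypothesis
  tests, whose exact form is unspecified.
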