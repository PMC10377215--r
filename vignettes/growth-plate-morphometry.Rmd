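---
title: "Growth-plate morphometry and the Area Ratio Index: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-plate morphometry and the Area Ratio Index: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physARI)
```

## The measurement

On coronal T2-weighted knee MRI the femoral growth plate (physis) appears as
a dark horizontal band between bright bone. As the skeleton matures the
band thins and finally closes, which makes its remaining extent a usable
marker of skeletal age in adolescents and young adults -- a population where
radiation-free age assessment matters.

The index computed here is a ratio of two areas measured on every slice
where the plate is clearly visible:

* `A_sf` -- the area of the distal femur *below* the plate, outlined
  manually (in this package: ingested as a binary mask, or simulated);
* `A_se` -- the area of the plate band itself, segmented semi-automatically
  (crop to a region of interest, range threshold, morphological cleanup).

Each area is `Pix_mm2 * N_pix`, with the pixel area taken from the DICOM
Pixel Spacing tag `[0028:0030]`. Summing over a subject's visible slices
gives `Af` and `Ae`, and the **Area Ratio Index** is

$$\mathrm{ARI} = \frac{A_f}{A_e}.$$

Because the denominator shrinks with maturation while the numerator does
not, ARI increases with age. The volumetric analogue
`VRI = (Af * Ts * Ns) / (Ae * Ts * Ns)` -- slice thickness `Ts` from tag
`[0018:0050]`, visible-slice count `Ns` -- is algebraically identical to
ARI, since both sums run over the same slices with the same thickness.
`measure_subject()` therefore evaluates VRI through that cancellation; the
alternative dimensional reading `V = A * Ts` (a sum of slabs, without the
`Ns` factor) is available via `volume_mode = "slab"` and changes neither
index, only the printed volumes. The as-printed convention is the default
for fidelity with the formula the method was published with; which of the
two the original authors intended is not decidable from the text, and the
ratio is insensitive to the choice.

## The synthetic cohort

No patient images are distributable, so the package ships a seeded phantom
generator whose defaults *are* the study conditions the pipeline is
validated under:

* **Anatomy.** A stylized distal femur in physical units: a 92 mm wide
  shaft/metaphysis block with two elliptical condyle lobes, centred in the
  field of view, with the intercondylar notch kept below the analysis
  window. A wavy dark band (amplitude 0.8 mm, wavelength 12 mm) crosses the
  bone; everything is specified in mm so the same anatomy is rendered on
  any device geometry.
* **Devices.** The three study scanners with their subject counts: Skyra
  3 T (11; 0.484--0.500 mm pixels, 320 x 320), Avanto 1.5 T (30;
  0.273--0.446 mm, 512 x 512), Panorama 1 T (9; 0.484--0.625 mm,
  288 x 288); 3 or 4 mm slices (mean 3.76). Cohorts draw devices with
  weights 11/30/9, per-subject pixel size uniformly within the device
  range, and 5--9 informative slices with mean near 7.
* **Age model.** Plate thickness `t(age) = max(t_min, t0 - k * age)` with
  `t0 = 4` mm, `k = 0.18` mm/yr, `t_min = 0.8` mm. The floor keeps the
  band at least one pixel per column even at the coarsest study sampling
  (0.625 mm) -- in vivo a near-fused physis remains visible through partial
  volume, and the published cohort had measurable plates on ~7 slices per
  subject up to age 26. The linear model itself is a modelling convenience:
  the source study does not quantify thickness against age.
* **Subject variability.** Cohorts jitter the per-subject thickness
  intercept (`sd` 0.25 mm). Without it the synthetic age--ARI correlation
  sits implausibly near 1; with it, plus device discretization and observer
  noise, cohort correlations land in the high-0.8s, the regime the method
  was reported in.
* **Intensities.** Background 0, bone 200, plate 40 on an 8-bit design
  scale, rendered at 12 bits (x16) with additive Gaussian noise
  (`noise_sd = 10` on the 8-bit scale, i.e. bone SNR 20). Quantization
  happens once, at render time, so DICOM write/read round trips are exactly
  identity.
* **Observers.** Three simulated raters re-draw the manual femur mask by
  displacing its boundary with a smooth random field bounded by
  `perturbation` (default 2 px), applied to the signed distance transform;
  different boundary segments move by different amounts and signs, like
  human tracing error. Zero perturbation reproduces the truth bit-exactly.

What the generator does **not** emulate: coil sensitivity profiles and bias
fields, Rician noise statistics, partial-volume graylevels (masks are
binary; band membership is decided at pixel centres), anatomy variation
beyond slice-width scaling, pathology, or motion. Green tests on phantoms
therefore demonstrate the *pipeline's* correctness and the method's
internal consistency, not clinical performance on real knees.

## Segmentation: choices in an under-specified recipe

The published method names the steps -- crop with a fixed bounding box,
range threshold, "filtering and morphological operations" -- but not the
parameter values. All of them are configuration here, with these defaults:

* **ROI.** A fixed central window of 70 mm (`default_roi_box()`), not a
  fixed pixel fraction: across the study's matrix/pixel-size combinations
  the field of view spans 139--228 mm, so the central 50% of *pixels*
  covers different anatomy per device and can admit background on
  wide-field series. At a typical 140--160 mm knee FOV the 70 mm window is
  the central ~50%, so the two conventions coincide where both are sane.
  For bare matrices without spacing the pixel convention is used.
* **Threshold.** `[min(ROI), alpha * T_otsu]` with `alpha = 0.6`: Otsu
  splits the bimodal plate/bone histogram and the fraction pulls the upper
  bound into the gap, selecting the dark-line class. Fixed `Tmin/Tmax` are
  available in the config.
* **Refinement.** An 8-connected minimum-component filter (20 px). Two
  classical steps are implemented but off by default, for a reason worth
  recording: a 3 x 3 median erodes the right-angle corners of a band's
  ends, and closing a cleanly thresholded band fills the 1-deep, 2-wide
  notches left wherever the wavy boundary's extremum grazes a pixel row.
  Either would break the package's noise-free contract (a zero-noise
  phantom is recovered *pixel-exactly* by the default chain). At the
  default noise level they are also unnecessary: measured Dice against
  truth is ~0.99 with or without them. Both remain one config key away for
  noisier data.
* **Connectivity.** Component labeling is 8-connected
  (`label_components()`), matching the MATLAB convention the original
  workflow used; under 4-connectivity a one-pixel staircase band -- exactly
  what a near-fused physis looks like -- falls apart into short runs that a
  size filter would delete.
* **Overlap.** Femur and plate masks are made disjoint by removing overlap
  from the femur mask: the plate boundary defines where "below the plate"
  starts, and the ratio's semantics require the two areas not to share
  pixels.

## Statistics

The cohort battery mirrors the published analysis: descriptive summaries
(mean, n-1 SD, t-based 95% CI, SEM, median, range), Lilliefors-corrected
Kolmogorov--Smirnov normality screening (the correction because mean and SD
are estimated from the sample; the source names only "Kolmogorov-Smirnov"),
Mann--Whitney U for sex differences, Pearson correlation of age with the
observer-averaged ARI (Fisher-z interval; at n = 3 or |r| = 1 the interval
is reported degenerate rather than fabricated), pixel-wise Cohen's kappa
between observer pairs, and an OLS regression of ARI on age, sex and seven
device characteristics (field strength, pixel size, matrix area, pixel
count, slice thickness, slice count, and total width `Ts * Ns`), with
partial correlations derived from the t statistics. Significance is 0.05,
two-sided, with no multiplicity correction -- matching the source analysis.

Kappa needs a substrate the source does not state (pixels? slices? binned
areas?). Here it is pixel labels within the cropped ROI: the full frame
would let the vast, trivially-agreed background inflate agreement toward 1
regardless of rater quality. The domain is a config key.

## Numerical choices

* Phantom band membership is evaluated per pixel centre against continuous
  boundary curves, so quantization error dithers along the wave instead of
  biasing band thickness; this is what keeps ARI stable (< 5% relative)
  between 0.273 mm and 0.625 mm pixels.
* VRI is computed through the algebraic cancellation of `Ts * Ns`;
  dividing the two stored volumes instead can differ in the final ulp.
* `ARI == nominal` checks on noise-free phantoms allow one part in 1e12:
  the pixel-area factor multiplies both sums and cancels exactly only in
  real arithmetic.
* DICOM decimal strings are written with `%.10g` and cohort pixel spacings
  are drawn at 3-decimal resolution, so geometry round-trips exactly.
* All randomness flows through one seeded generator per entry point;
  identical seeds give bit-identical phantoms, masks, DICOM bytes and
  report files. RNG state of the caller is always restored.

## Problem sizes

The test suite exercises unit fixtures on a 256 x 256, 0.5 mm synthetic
device and runs the full pipeline at the study scale (50 subjects, three
observers, ~340 slices) once; the acceptance script repeats the 50-subject
run plus six noise-free recovery phantoms and the two extreme-pixel-size
renders. These sizes were chosen as the smallest that still exercise every
study condition (all three devices, the full age range, slice-count
variation) at the published cohort size.

## Known limitations

* Exact noise-free recovery is guaranteed for bands of at least one pixel
  per column (all study devices under the default age model); sub-pixel
  bands render as dashed lines whose fragments the size filter removes --
  by design, since such slices would not be called "clearly visible".
* The femur mask is taken as given (manual input or simulated observer);
  no automatic femur segmentation is attempted.
* Volumes use the as-printed formula by default (see above); only the
  ratio is invariant to that choice.
* Single-frame, uncompressed, Explicit-VR-little-endian DICOM only; that
  is what the writer produces and what the study's tag set needs.
* The age model and its parameters are phantom conveniences. Nothing here
  validates ARI against real chronological age; the package demonstrates
  that *if* plates thin with age, this pipeline measures it consistently
  across devices and observers.
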