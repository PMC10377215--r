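# physARI

Growth-plate morphometry and the **Area Ratio Index (ARI)** from coronal
T2-weighted knee MRI, for skeletal age estimation.

On T2WI the femoral growth plate (physis) is a dark band between bright
bone that thins and closes as the skeleton matures. For every slice where
the plate is clearly visible, two binary masks are measured: the distal
femur below the plate (area `A_sf`, drawn manually) and the plate band
itself (area `A_se`, segmented semi-automatically by ROI crop -> range
threshold -> morphological cleanup). Areas come from pixel counts times the
pixel area in the DICOM Pixel Spacing tag `[0028:0030]`. Summed over a
subject's visible slices,

```
ARI = Af / Ae,        Af = sum_s A_sf,   Ae = sum_s A_se
VRI = (Af * Ts * Ns) / (Ae * Ts * Ns) = ARI
```

with slice thickness `Ts` (`[0018:0050]`) and visible-slice count `Ns`.
ARI grows with age as the plate shrinks, and is designed to be insensitive
to which MRI device produced the images.

The package is aimed at researchers in forensic age assessment and
skeletal-maturation imaging who want the full measurement chain as tested,
scriptable code:

* `generate_subject()` / `generate_cohort()` / `simulate_observer_masks()` —
  a seeded synthetic knee-phantom generator (age-dependent plate thickness,
  the three study scanner profiles, simulated manual observers) standing in
  for non-distributable patient data;
* `read_slice()` / `write_cohort_dicom()` / `load_subject()` — minimal
  DICOM I/O (uncompressed monochrome, Explicit VR little endian) exposing
  exactly the tags the formulas consume;
* `segment_growth_plate()`, `auto_threshold()`, `refine_mask()`,
  `load_femur_mask()` — the semi-automatic plate segmentation;
* `measure_subject()`, `compute_ari()`, `compute_volumes()` — the
  morphometry;
* `pearson_r_ci()`, `cohen_kappa()`, `mann_whitney_u()`, `ks_normality()`,
  `multiple_regression()`, `cohort_summary()` — the cohort statistics
  (age–ARI correlation, inter-observer agreement, device-influence
  regression, descriptives);
* `run_pipeline()` — the end-to-end run (simulate or ingest -> segment ->
  measure -> report), plus a thin CLI at `inst/cli/physari.R`.

## Worked example

```r
library(physARI)

ph <- generate_subject(phantom_spec(age = 14, sex = "F",
                                    device = knee_mri_devices()$avanto,
                                    seed = 42))
ph$study
#> <subject_study> S001: F, 14.0 y, 7 slices on Avanto, Siemens

obs <- simulate_observer_masks(ph$truth, perturbation = 2, seed = 42)
m <- measure_subject(ph$study, segmentation_result("Obs1", obs[[1]]$femur_masks))
m
#> <subject_morphometry> S001 (Obs1): Ns=7, Af=22920.5 mm2, Ae=588.6 mm2, ARI=38.938

round(c(ARI = m$ARI, nominal = ph$truth$nominal_ARI), 3)
#>     ARI nominal
#>  38.938  38.932
```

The subject's seven slices contribute 22 920.5 mm² of femur below the plate
and 588.6 mm² of plate band, giving ARI = 38.94 — within 0.02% of the
generator's ground-truth value, with the plate segmented automatically and
the femur mask perturbed by a simulated human observer.

A full cohort run (50 subjects, 3 observers, reports as CSV/JSON plus
outline overlays):

```r
res <- run_pipeline(list(seed = 1, out_dir = "runs/demo"))
res$correlation   # age-ARI Pearson r with Fisher-z CIs: Female / Male / Total
res$kappa         # pairwise observer agreement within the ROI
res$regression    # ARI ~ age + sex + device characteristics
```

or from a shell: `Rscript inst/cli/physari.R --simulate 50 --seed 1 --out runs/demo`.

## Design notes

The methods vignette (`vignettes/growth-plate-morphometry.Rmd`) documents
the model and its assumptions, what the phantom generator does and does not
emulate, the segmentation defaults chosen where the published recipe is
silent (ROI as a fixed 70 mm central window, Otsu-fraction threshold,
8-connected component filtering), and the package's numerical conventions.
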