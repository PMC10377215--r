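Package: physARI
Title: Growth-Plate Morphometry and the Area Ratio Index from Knee MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Semi-automatic morphometry of the distal femoral growth plate
    (physis) on coronal T2-weighted knee MRI for skeletal age estimation.
    Segments the growth-plate band by region-of-interest cropping, range
    thresholding and morphological refinement, converts binary masks to
    physical areas using DICOM Pixel Spacing metadata, and computes the
    Area Ratio Index (ARI, femur-below-plate area over plate area) and its
    volumetric counterpart (VRI) per subject. Includes a seeded synthetic
    knee-phantom generator with ground-truth masks and simulated observers,
    a minimal DICOM reader/writer for uncompressed monochrome slices, and
    the cohort statistics used in this setting: descriptive summaries,
    Lilliefors-corrected Kolmogorov-Smirnov normality tests, Mann-Whitney U,
    Pearson correlation with Fisher-z intervals, pixel-wise Cohen's kappa
    between observers, and multiple regression of ARI on device
    characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    nortest,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
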