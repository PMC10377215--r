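#' Specification of one synthetic knee phantom
#'
#' Parameters for rendering one subject's stack of coronal knee slices:
#' demographics, acquisition device, slice count, the age model of the
#' growth-plate thickness and the additive noise level.
#'
#' The plate thickness follows `t(age) = max(t_min, t0 - k * age)` (mm), a
#' linear thinning that never reaches zero: the generated physis narrows
#' with maturation but never fully fuses, keeping the Area Ratio Index
#' finite. Fully fused plates are exercised separately through the
#' morphometry error paths.
#'
#' @param age Age at examination in years; the study range is 10--26.
#' @param sex `"F"` or `"M"`.
#' @param device A [device_profile()].
#' @param n_slices Number of coronal slices through the knee (default 7,
#'   the typical number of slices on which the plate is clearly visible).
#' @param plate_thickness_model Named list or vector with `t0` (plate
#'   thickness extrapolated to age 0, mm), `k` (thinning rate, mm/year) and
#'   `t_min` (residual thickness floor, mm > 0).
#' @param noise_sd Standard deviation of additive Gaussian intensity noise,
#'   on the 8-bit design scale where background = 0, plate = 40, bone = 200.
#' @param seed Integer seed; identical specs with identical seeds render
#'   bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @examples
#' phantom_spec(age = 14, sex = "F", device = knee_mri_devices()$avanto, seed = 1)
#' @export
phantom_spec <- function(age, sex = c("F", "M"), device, n_slices = 7,
                         plate_thickness_model = c(t0 = 4, k = 0.18, t_min = 0.8),
                         noise_sd = 10, seed = 1) {
  sex <- match.arg(sex)
  ptm <- as.list(plate_thickness_model)
  if (!all(c("t0", "k", "t_min") %in% names(ptm)))
    stop_physari("plate_thickness_model needs t0, k and t_min",
                 class = "physari_validation_error")
  if (!is.finite(age) || age <= 0)
    stop_physari("age must be a positive number of years",
                 class = "physari_validation_error")
  if (!inherits(device, "device_profile"))
    stop_physari("device must be a device_profile", class = "physari_validation_error")
  if (n_slices < 1)
    stop_physari("n_slices must be >= 1", class = "physari_validation_error")
  if (ptm$t_min <= 0)
    stop_physari("t_min must be > 0: the generated plate never fully fuses",
                 class = "physari_validation_error")
  if (ptm$k < 0 || ptm$t0 <= 0)
    stop_physari("plate thickness model needs t0 > 0 and k >= 0",
                 class = "physari_validation_error")
  if (noise_sd < 0)
    stop_physari("noise_sd must be >= 0", class = "physari_validation_error")
  structure(
    list(
      age = as.numeric(age), sex = sex, device = device,
      n_slices = as.integer(n_slices),
      plate_thickness_model = lapply(ptm[c("t0", "k", "t_min")], as.numeric),
      noise_sd = as.numeric(noise_sd), seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

#' Growth-plate thickness at a given age
#'
#' Evaluates the phantom's linear thinning model
#' `t(age) = max(t_min, t0 - k * age)`.
#'
#' @param age Years.
#' @param model Named list/vector with `t0`, `k`, `t_min` (mm, mm/year, mm).
#' @return Thickness in mm.
#' @export
plate_thickness <- function(age, model = c(t0 = 4, k = 0.18, t_min = 0.8)) {
  m <- as.list(model)
  pmax(m$t_min, m$t0 - m$k * age)
}

# Fixed phantom anatomy, in mm relative to the image centre (rows grow
# downward). The distal femur is a stylized bicondylar silhouette: a
# rectangular shaft/metaphysis block with two elliptical condyle lobes at
# the bottom; the intercondylar notch sits entirely below the central
# 50% x 50% ROI window so the default crop contains bone and plate only.
phantom_geometry <- function() {
  list(
    rect_rows = c(-50, 46), rect_halfwidth = 46,
    condyle_row = 44, condyle_col = 22, condyle_ax = c(14, 24),
    plate_row = 18, plate_halfwidth = 30,
    wave_amp = 0.8, wave_len = 12,
    width_mod = 0.3,
    bone_intensity = 200, plate_intensity = 40, bit_scale = 16
  )
}

# Render one coronal slice. All geometry is specified in mm so the same
# anatomy discretizes consistently across devices with different pixel
# spacings; band membership is evaluated per pixel centre against
# continuous boundary curves, which dithers the quantization error along
# the wavy plate boundary instead of biasing the band thickness.
render_phantom_slice <- function(device, t_mm, phase, width_scale, noise_sd) {
  g <- phantom_geometry()
  R <- device$matrix_size[1]; C <- device$matrix_size[2]
  sp <- device$pixel_spacing
  yr <- (seq_len(R) - 0.5 - R / 2) * sp[1]
  xc <- (seq_len(C) - 0.5 - C / 2) * sp[2]
  w <- width_scale

  rect <- outer(yr >= g$rect_rows[1] & yr <= g$rect_rows[2],
                abs(xc) <= g$rect_halfwidth * w)
  ell <- function(cx) {
    outer(((yr - g$condyle_row) / g$condyle_ax[1])^2,
          ((xc - cx * w) / (g$condyle_ax[2] * w))^2, "+") <= 1
  }
  sil <- rect | ell(g$condyle_col) | ell(-g$condyle_col)

  lower <- g$plate_row + g$wave_amp * sin(2 * pi * xc / g$wave_len + phase)
  in_band_cols <- matrix(abs(xc) <= g$plate_halfwidth * w, R, C, byrow = TRUE)
  below_lower <- outer(yr, lower, ">=")
  plate <- sil & !below_lower & outer(yr, lower - t_mm, ">=") & in_band_cols
  femur <- sil & below_lower

  I <- matrix(0, R, C)
  I[sil] <- g$bone_intensity
  I[plate] <- g$plate_intensity
  if (noise_sd > 0) I <- I + matrix(rnorm(R * C, sd = noise_sd), R, C)
  pixels <- matrix(as.integer(round(pmin(pmax(I, 0), 255) * g$bit_scale)), R, C)

  list(pixels = pixels,
       femur_mask = as_binary_mask(femur),
       plate_mask = as_binary_mask(plate))
}

#' Generate one synthetic knee subject with ground truth
#'
#' Renders a stack of coronal slices for one subject: bright distal-femur
#' bone (bicondylar silhouette), a dark horizontal growth-plate band of
#' age-dependent thickness with a wavy boundary, dark background and
#' additive Gaussian noise. Slices sample the knee front-to-back, so the
#' silhouette is widest for central slices. Alongside the images, pixel-true
#' ground-truth masks are returned: the femur below the plate (the region a
#' manual observer would outline) and the plate band itself, together with
#' the nominal Area Ratio Index computed from those masks.
#'
#' @param spec A [phantom_spec()].
#' @param subject_id Subject identifier stored in the study.
#' @return A list with components `study` (class `subject_study`: id, age,
#'   sex, device and the ordered [knee_slice] stack) and `truth` (class
#'   `ground_truth`: `femur_masks`, `plate_masks`, `nominal_ARI`).
#' @examples
#' ph <- generate_subject(phantom_spec(age = 12, device = knee_mri_devices()$skyra,
#'                                     seed = 7))
#' ph$truth$nominal_ARI
#' @export
generate_subject <- function(spec, subject_id = "S001") {
  if (!inherits(spec, "phantom_spec"))
    stop_physari("spec must be a phantom_spec", class = "physari_validation_error")
  g <- phantom_geometry()
  t_mm <- plate_thickness(spec$age, spec$plate_thickness_model)
  n <- spec$n_slices
  with_seed(spec$seed, {
    phases <- runif(n, 0, 2 * pi)
    pos <- if (n == 1) 0 else (2 * seq_len(n) - n - 1) / (n - 1) * 0.8
    scales <- sqrt(1 - g$width_mod * pos^2)
    slices <- vector("list", n)
    femur_masks <- vector("list", n)
    plate_masks <- vector("list", n)
    for (s in seq_len(n)) {
      r <- render_phantom_slice(spec$device, t_mm, phases[s], scales[s], spec$noise_sd)
      slices[[s]] <- knee_slice(
        pixels = r$pixels,
        pixel_spacing = spec$device$pixel_spacing,
        slice_thickness = spec$device$slice_thickness,
        slice_index = s - 1L
      )
      femur_masks[[s]] <- r$femur_mask
      plate_masks[[s]] <- r$plate_mask
    }
    n_f <- sum(vapply(femur_masks, sum, numeric(1)))
    n_e <- sum(vapply(plate_masks, sum, numeric(1)))
    truth <- structure(
      list(femur_masks = femur_masks, plate_masks = plate_masks,
           nominal_ARI = n_f / n_e),
      class = "ground_truth"
    )
    study <- subject_study(subject_id, spec$age, spec$sex, slices, spec$device)
    list(study = study, truth = truth)
  })
}

#' Generate a synthetic study cohort
#'
#' Draws a cohort emulating the study population: ages uniform over
#' `age_range`, balanced sexes, devices drawn from `device_mix` (default:
#' the study's 11/30/9 split over Skyra 3 T, Avanto 1.5 T and
#' Panorama 1 T), per-subject pixel spacing uniform within each device's
#' operating range, slice thickness 3 or 4 mm, and 5--9 informative slices
#' per subject (mean close to 7). Subject-level biology is represented by a
#' Gaussian jitter of the plate-thickness intercept (`plate_jitter_sd`),
#' without which the synthetic age--ARI correlation would be implausibly
#' close to 1.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param age_range Length-2 numeric within (5, 40), min < max.
#' @param device_mix Named weights over the profiles of
#'   [knee_mri_devices()].
#' @param seed Integer seed for the whole cohort.
#' @param plate_jitter_sd SD (mm) of the per-subject plate-thickness
#'   intercept jitter.
#' @param noise_sd Per-slice additive noise SD passed to [phantom_spec()].
#' @param plate_thickness_model Thickness model passed to [phantom_spec()].
#' @return List of per-subject lists `(study, truth)` as returned by
#'   [generate_subject()].
#' @examples
#' coh <- generate_cohort(4, seed = 1)
#' sapply(coh, function(s) s$study$age)
#' @export
generate_cohort <- function(n_subjects, age_range = c(10, 26),
                            device_mix = default_device_mix(), seed = 1,
                            plate_jitter_sd = 0.25, noise_sd = 10,
                            plate_thickness_model = c(t0 = 4, k = 0.18, t_min = 0.8)) {
  if (n_subjects < 2)
    stop_physari("n_subjects must be >= 2", class = "physari_validation_error")
  if (length(age_range) != 2 || age_range[1] >= age_range[2] ||
      age_range[1] <= 5 || age_range[2] >= 40)
    stop_physari("age_range must be an increasing pair within (5, 40)",
                 class = "physari_validation_error")
  devices <- knee_mri_devices()
  if (!all(names(device_mix) %in% names(devices)))
    stop_physari("device_mix names must match knee_mri_devices()",
                 class = "physari_validation_error")
  ptm <- as.list(plate_thickness_model)
  with_seed(seed, {
    ages <- runif(n_subjects, age_range[1], age_range[2])
    sexes <- rep(c("F", "M"), length.out = n_subjects)[sample.int(n_subjects)]
    dev_names <- sample(names(device_mix), n_subjects, replace = TRUE,
                        prob = device_mix)
    lapply(seq_len(n_subjects), function(i) {
      base <- devices[[dev_names[i]]]
      spacing <- if (is.null(base$pixel_size_range)) base$pixel_spacing[1] else
        round(runif(1, base$pixel_size_range[1], base$pixel_size_range[2]), 3)
      dev_i <- device_profile(base$name, base$field_strength, spacing,
                              base$matrix_size,
                              slice_thickness = sample(c(3, 4), 1, prob = c(0.24, 0.76)),
                              pixel_size_range = base$pixel_size_range)
      t0_i <- max(ptm$t_min + 1e-6, ptm$t0 + rnorm(1, 0, plate_jitter_sd))
      spec_i <- phantom_spec(
        age = ages[i], sex = sexes[i], device = dev_i,
        n_slices = sample(5:9, 1, prob = c(0.06, 0.27, 0.45, 0.16, 0.06)),
        plate_thickness_model = c(t0 = t0_i, k = ptm$k, t_min = ptm$t_min),
        noise_sd = noise_sd,
        seed = sample.int(.Machine$integer.max - 1L, 1)
      )
      generate_subject(spec_i, subject_id = sprintf("S%03d", i))
    })
  })
}

#' Simulate observers re-drawing the manual femur mask
#'
#' Emulates independent human observers performing the manual femur
#' segmentation: each observer's mask is the ground-truth femur mask with
#' its boundary locally displaced inward or outward by up to `perturbation`
#' pixels. The displacement is a smooth random field applied to the signed
#' distance transform of the truth mask, so different boundary segments
#' move by different amounts and signs, as human tracing error does.
#' `perturbation = 0` reproduces the truth exactly.
#'
#' @param truth A `ground_truth` object from [generate_subject()].
#' @param perturbation Maximum boundary displacement in pixels (>= 0).
#' @param seed Integer seed.
#' @param n_observers Number of observers (default 3, as in the study).
#' @param observer_ids Labels; default `Obs1..ObsN`.
#' @return List of `segmentation_result` objects, one per observer, each
#'   with `observer_id` and per-slice `femur_masks` (plate masks are left
#'   `NULL`: the plate is segmented semi-automatically from the image, not
#'   redrawn by the observer).
#' @examples
#' ph <- generate_subject(phantom_spec(age = 12, device = knee_mri_devices()$skyra,
#'                                     seed = 3))
#' obs <- simulate_observer_masks(ph$truth, perturbation = 2, seed = 9)
#' length(obs)
#' @export
simulate_observer_masks <- function(truth, perturbation = 2, seed = 1,
                                    n_observers = 3,
                                    observer_ids = paste0("Obs", seq_len(n_observers))) {
  if (!inherits(truth, "ground_truth"))
    stop_physari("truth must be a ground_truth", class = "physari_validation_error")
  if (perturbation < 0)
    stop_physari("perturbation must be >= 0", class = "physari_validation_error")
  with_seed(seed, {
    lapply(seq_len(n_observers), function(o) {
      masks <- lapply(truth$femur_masks, function(m) {
        if (perturbation == 0) return(m)
        d <- EBImage::distmap(m) - EBImage::distmap(1L - m)
        eta <- matrix(runif(64, -perturbation, perturbation), 8, 8)
        eta <- EBImage::resize(eta, w = nrow(m), h = ncol(m))
        as_binary_mask((d + eta) > 0)
      })
      segmentation_result(observer_ids[o], femur_masks = masks)
    })
  })
}

#' Container for one observer's per-slice segmentation masks
#'
#' @param observer_id Observer label.
#' @param femur_masks List of per-slice binary femur-below-plate masks.
#' @param plate_masks Optional list of per-slice binary plate masks in
#'   full-frame coordinates.
#' @return Object of class `segmentation_result`.
#' @export
segmentation_result <- function(observer_id, femur_masks, plate_masks = NULL) {
  stopifnot(is.character(observer_id), length(observer_id) == 1, is.list(femur_masks))
  if (!is.null(plate_masks) && length(plate_masks) != length(femur_masks))
    stop_physari("plate_masks must match femur_masks in length",
                 class = "physari_validation_error")
  structure(
    list(observer_id = observer_id, femur_masks = femur_masks,
         plate_masks = plate_masks),
    class = "segmentation_result"
  )
}
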