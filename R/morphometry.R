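#' Pixel count and physical area of a binary mask
#'
#' Converts a segmentation mask to a physical area: the positive-pixel
#' count times the single-pixel area, `A = Pix_mm2 x N_pix`.
#'
#' @param mask Binary matrix.
#' @param pix_area Single-pixel area in mm^2 (> 0), from [pixel_area()].
#' @return List with `n_pix` and `area` (mm^2).
#' @examples
#' mask_area(matrix(c(1, 1, 0, 0), 2, 2), 0.25)
#' @export
mask_area <- function(mask, pix_area) {
  if (!is.finite(pix_area) || pix_area <= 0)
    stop_physari("pix_area must be > 0", class = "physari_validation_error")
  n <- sum(as_binary_mask(mask))
  list(n_pix = n, area = pix_area * n)
}

#' Per-subject totals of the slice areas
#'
#' Sums the femur-below-plate and plate areas over a subject's visible
#' slices: `Af = A_sf1 + A_sf2 + ...`, `Ae = A_se1 + A_se2 + ...`.
#'
#' @param per_slice Data frame with columns `A_sf` and `A_se` (one row per
#'   visible slice), as produced by [measure_subject()].
#' @return List with `Af` and `Ae` (mm^2).
#' @export
subject_totals <- function(per_slice) {
  if (NROW(per_slice) == 0)
    stop_physari("no visible slices: cannot total areas",
                 class = "physari_validation_error")
  list(Af = sum(per_slice$A_sf), Ae = sum(per_slice$A_se))
}

#' Area Ratio Index
#'
#' `ARI = Af / Ae`: the total femur-below-plate area over the total plate
#' area. As the physis thins and closes with skeletal maturation, `Ae`
#' shrinks while `Af` does not, so ARI grows with age. A fully fused plate
#' (`Ae = 0`) leaves the index undefined and raises a fused-plate error.
#'
#' @param Af Total femur-below-plate area, mm^2 (>= 0).
#' @param Ae Total plate area, mm^2 (> 0).
#' @return Dimensionless ratio.
#' @examples
#' compute_ari(150, 15) # 10
#' @export
compute_ari <- function(Af, Ae) {
  if (Af < 0) stop_physari("Af must be >= 0", class = "physari_validation_error")
  if (Ae == 0)
    stop_physari("plate area is zero: ARI undefined for a fully fused physis",
                 class = "physari_fused_plate_error")
  if (Ae < 0) stop_physari("Ae must be >= 0", class = "physari_validation_error")
  Af / Ae
}

#' Volumes from total areas, slice thickness and slice count
#'
#' `Vf = Af x Ts x Ns` and `Ve = Ae x Ts x Ns`, with `Ts` the slice
#' thickness (mm) and `Ns` the number of slices on which the plate was
#' visible. With `mode = "slab"` the alternative dimensional reading
#' `V = A x Ts` (sum of slabs, no `Ns` factor) is used instead; the choice
#' never affects the volume ratio, since the common factor cancels.
#'
#' @param Af,Ae Total areas in mm^2.
#' @param Ts Slice thickness in mm (> 0).
#' @param Ns Number of visible slices (>= 1).
#' @param mode `"as-printed"` (default, `A x Ts x Ns`) or `"slab"`
#'   (`A x Ts`).
#' @return List with `Vf` and `Ve` (mm^3).
#' @export
compute_volumes <- function(Af, Ae, Ts, Ns, mode = c("as-printed", "slab")) {
  mode <- match.arg(mode)
  if (!is.finite(Ts) || Ts <= 0)
    stop_physari("Ts must be > 0", class = "physari_validation_error")
  if (Ns < 1) stop_physari("Ns must be >= 1", class = "physari_validation_error")
  f <- if (mode == "as-printed") Ts * Ns else Ts
  list(Vf = Af * f, Ve = Ae * f)
}

#' Volume Ratio Index
#'
#' `VRI = Vf / Ve`. Built from the same areas, slice thickness and slice
#' count, the common factor cancels and VRI is mathematically identical to
#' ARI. [measure_subject()] therefore evaluates VRI through the
#' cancellation (bit-identical to ARI by construction); this standalone
#' helper divides whatever volumes it is given, so it agrees with ARI to
#' floating-point precision rather than bitwise.
#'
#' @param Vf,Ve Volumes in mm^3, `Ve > 0`.
#' @return Dimensionless ratio.
#' @export
compute_vri <- function(Vf, Ve) {
  if (Ve == 0)
    stop_physari("plate volume is zero: VRI undefined for a fully fused physis",
                 class = "physari_fused_plate_error")
  Vf / Ve
}

#' Full morphometry of one subject under one observer's masks
#'
#' Selects the slices where the plate is visible, measures per-slice areas
#' from the femur and plate masks using the slice's pixel area, totals them
#' and derives ARI, volumes and VRI. Overlapping femur/plate pixels are
#' resolved in favor of the plate (removed from the femur mask) so the two
#' areas stay disjoint, as the ratio's semantics require.
#'
#' @param study A [subject_study()].
#' @param seg A [segmentation_result()] whose masks align with the slices;
#'   if its `plate_masks` is `NULL`, plates are segmented from the images
#'   with [segment_growth_plate()] using `box`, `spec` and `refine`.
#' @param visibility_min Minimum plate pixels for a slice to count
#'   (default 20).
#' @param box,spec,refine,otsu_fraction Passed to [segment_growth_plate()]
#'   when plate masks are not supplied.
#' @param volume_mode Passed to [compute_volumes()].
#' @return Object of class `subject_morphometry`: `subject_id`,
#'   `observer_id`, `per_slice` data frame (slice_index, N_pix_f, N_pix_e,
#'   A_sf, A_se), `Af`, `Ae`, `ARI`, `Ts`, `Ns`, `Vf`, `Ve`, `VRI`.
#' @export
measure_subject <- function(study, seg, visibility_min = 20,
                            box = NULL, spec = NULL, refine = refine_params(),
                            otsu_fraction = 0.6,
                            volume_mode = c("as-printed", "slab")) {
  stopifnot(inherits(study, "subject_study"), inherits(seg, "segmentation_result"))
  volume_mode <- match.arg(volume_mode)
  n <- length(study$slices)
  if (length(seg$femur_masks) != n)
    stop_physari("segmentation masks do not align with the slice stack",
                 class = "physari_consistency_error")
  rows <- list()
  for (s in seq_len(n)) {
    sl <- study$slices[[s]]
    plate <- if (!is.null(seg$plate_masks)) seg$plate_masks[[s]] else
      segment_growth_plate(sl, box = box, spec = spec, refine = refine,
                           otsu_fraction = otsu_fraction)
    if (!all(dim(plate) == dim(sl$pixels)))
      stop_physari("plate mask shape does not match slice",
                   class = "physari_consistency_error")
    if (!is_plate_visible(plate, visibility_min)) next
    femur <- as_binary_mask(seg$femur_masks[[s]])
    femur[plate == 1L] <- 0L
    pa <- pixel_area(sl)
    af <- mask_area(femur, pa)
    ae <- mask_area(plate, pa)
    rows[[length(rows) + 1L]] <- data.frame(
      slice_index = sl$slice_index, N_pix_f = af$n_pix, N_pix_e = ae$n_pix,
      A_sf = af$area, A_se = ae$area)
  }
  if (length(rows) == 0)
    stop_physari("no slices with a visible growth plate for subject ",
                 study$subject_id, class = "physari_validation_error")
  per_slice <- do.call(rbind, rows)
  tot <- subject_totals(per_slice)
  Ts <- study$slices[[1]]$slice_thickness
  Ns <- nrow(per_slice)
  ari <- compute_ari(tot$Af, tot$Ae)
  vol <- compute_volumes(tot$Af, tot$Ae, Ts, Ns, mode = volume_mode)
  # VRI = (Af*Ts*Ns)/(Ae*Ts*Ns): the common factor cancels algebraically, so
  # the index is evaluated through the cancellation and is identical to ARI
  # by construction -- literal floating-point division of the two volumes
  # could differ in the last ulp.
  structure(
    list(subject_id = study$subject_id, observer_id = seg$observer_id,
         age = study$age, sex = study$sex, device = study$device,
         per_slice = per_slice, Af = tot$Af, Ae = tot$Ae, ARI = ari,
         Ts = Ts, Ns = Ns, Vf = vol$Vf, Ve = vol$Ve,
         VRI = ari),
    class = "subject_morphometry"
  )
}

#' @export
print.subject_morphometry <- function(x, ...) {
  cat(sprintf("<subject_morphometry> %s (%s): Ns=%d, Af=%.1f mm2, Ae=%.1f mm2, ARI=%.3f\n",
              x$subject_id, x$observer_id, x$Ns, x$Af, x$Ae, x$ARI))
  invisible(x)
}

#' Flatten subject morphometries to one row per subject x observer
#'
#' @param morphs List of `subject_morphometry` objects.
#' @return Data frame with subject_id, observer_id, age, sex, device
#'   covariates, Ns, Ts, Af, Ae, ARI, Vf, Ve, VRI.
#' @export
morphometry_table <- function(morphs) {
  do.call(rbind, lapply(morphs, function(m) {
    data.frame(
      subject_id = m$subject_id, observer_id = m$observer_id,
      age = m$age, sex = m$sex, device = m$device$name,
      field_strength = m$device$field_strength,
      pixel_size_mm2 = prod(m$device$pixel_spacing),
      n_pixels = prod(m$device$matrix_size),
      matrix_area_mm2 = prod(m$device$matrix_size) * prod(m$device$pixel_spacing),
      Ns = m$Ns, Ts = m$Ts, Af = m$Af, Ae = m$Ae, ARI = m$ARI,
      Vf = m$Vf, Ve = m$Ve, VRI = m$VRI,
      total_width = m$Ts * m$Ns,
      stringsAsFactors = FALSE)
  }))
}
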