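#' MRI device acquisition profile
#'
#' Describes the acquisition geometry of one MRI scanner configuration:
#' field strength, in-plane pixel spacing, image matrix and slice thickness.
#' These are the quantities the morphometry consumes (pixel area, slice
#' thickness) plus the device covariates entering the regression analysis.
#'
#' @param name Device label, e.g. `"Avanto, Siemens"`.
#' @param field_strength Static magnetic field in tesla (> 0).
#' @param pixel_spacing Numeric pair `(row, col)` in mm, both > 0. A single
#'   value is recycled to an isotropic pair.
#' @param matrix_size Integer pair `(rows, cols)`, each >= 64.
#' @param slice_thickness Slice thickness in mm (> 0).
#' @param pixel_size_range Optional numeric pair: the range of isotropic
#'   pixel sizes (mm) this device was operated at; used by
#'   [generate_cohort()] to draw per-subject spacings.
#' @return An object of class `device_profile`.
#' @examples
#' device_profile("Avanto, Siemens", 1.5, 0.273, c(512, 512), 4)
#' @export
device_profile <- function(name, field_strength, pixel_spacing, matrix_size,
                           slice_thickness, pixel_size_range = NULL) {
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  stopifnot(
    is.character(name), length(name) == 1,
    length(pixel_spacing) == 2, length(matrix_size) == 2
  )
  if (!is.finite(field_strength) || field_strength <= 0)
    stop_physari("field_strength must be > 0", class = "physari_validation_error")
  if (any(!is.finite(pixel_spacing)) || any(pixel_spacing <= 0))
    stop_physari("pixel_spacing values must be > 0", class = "physari_validation_error")
  if (any(matrix_size < 64))
    stop_physari("matrix_size must be at least 64 x 64", class = "physari_validation_error")
  if (!is.finite(slice_thickness) || slice_thickness <= 0)
    stop_physari("slice_thickness must be > 0", class = "physari_validation_error")
  structure(
    list(
      name = name,
      field_strength = as.numeric(field_strength),
      pixel_spacing = as.numeric(pixel_spacing),
      matrix_size = as.integer(matrix_size),
      slice_thickness = as.numeric(slice_thickness),
      pixel_size_range = if (is.null(pixel_size_range)) NULL else as.numeric(pixel_size_range)
    ),
    class = "device_profile"
  )
}

#' @export
print.device_profile <- function(x, ...) {
  cat(sprintf(
    "<device_profile> %s: %.1f T, %.3f x %.3f mm, %d x %d px, %.1f mm slices\n",
    x$name, x$field_strength, x$pixel_spacing[1], x$pixel_spacing[2],
    x$matrix_size[1], x$matrix_size[2], x$slice_thickness
  ))
  invisible(x)
}

#' Scanner profiles of the study devices
#'
#' The three scanner configurations used in the study cohort, with the
#' number of subjects examined on each: Skyra 3 T (11 subjects,
#' 0.484--0.500 mm pixels, 320 x 320), Avanto 1.5 T (30 subjects,
#' 0.273--0.446 mm, 512 x 512) and Panorama 1.0 T (9 subjects,
#' 0.484--0.625 mm, 288 x 288), all with 3--4 mm slices. The nominal
#' `pixel_spacing` of each profile is the midpoint of its pixel-size range;
#' [generate_cohort()] draws per-subject spacings uniformly over the range.
#'
#' @return Named list of [device_profile()] objects; each carries an
#'   attribute `n_subjects` with the study headcount.
#' @examples
#' names(knee_mri_devices())
#' @export
knee_mri_devices <- function() {
  dev <- list(
    skyra = device_profile("Skyra, Siemens", 3.0, 0.492, c(320, 320), 4,
                           pixel_size_range = c(0.484, 0.500)),
    avanto = device_profile("Avanto, Siemens", 1.5, 0.360, c(512, 512), 4,
                            pixel_size_range = c(0.273, 0.446)),
    panorama = device_profile("Panorama, Philips", 1.0, 0.555, c(288, 288), 4,
                              pixel_size_range = c(0.484, 0.625))
  )
  attr(dev$skyra, "n_subjects") <- 11L
  attr(dev$avanto, "n_subjects") <- 30L
  attr(dev$panorama, "n_subjects") <- 9L
  dev
}

#' Default device sampling weights of the study cohort
#'
#' Subject counts per scanner (11 Skyra, 30 Avanto, 9 Panorama) normalized
#' to sampling weights for [generate_cohort()].
#' @return Named numeric vector summing to 1.
#' @export
default_device_mix <- function() {
  c(skyra = 11, avanto = 30, panorama = 9) / 50
}
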