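#' One coronal knee slice with its geometric metadata
#'
#' The unit record of the morphometry: a rectangular grid of grayscale
#' intensities plus the DICOM-derived geometry the area formulas consume --
#' Pixel Spacing (the physical centre-to-centre distance between pixels, a
#' row/column pair in mm) and Slice Thickness.
#'
#' @param pixels Non-empty numeric/integer matrix of intensities.
#' @param pixel_spacing Numeric pair `(row, col)` in mm, both > 0.
#' @param slice_thickness Slice thickness in mm (> 0).
#' @param slice_index 0-based index of the slice within its subject.
#' @param source_path Optional originating file path.
#' @param field_strength Optional magnetic field strength in tesla.
#' @param subject_id,sex Optional identity metadata carried from DICOM.
#' @return Object of class `knee_slice`.
#' @export
knee_slice <- function(pixels, pixel_spacing, slice_thickness, slice_index = 0L,
                       source_path = NA_character_, field_strength = NA_real_,
                       subject_id = NA_character_, sex = NA_character_) {
  if (!is.matrix(pixels) || length(pixels) == 0)
    stop_physari("pixels must be a non-empty matrix", class = "physari_validation_error")
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  if (length(pixel_spacing) != 2 || any(!is.finite(pixel_spacing)) ||
      any(pixel_spacing <= 0))
    stop_physari("pixel_spacing must be a positive (row, col) pair in mm",
                 class = "physari_validation_error")
  if (!is.finite(slice_thickness) || slice_thickness <= 0)
    stop_physari("slice_thickness must be > 0", class = "physari_validation_error")
  structure(
    list(pixels = pixels, pixel_spacing = as.numeric(pixel_spacing),
         slice_thickness = as.numeric(slice_thickness),
         slice_index = as.integer(slice_index),
         source_path = source_path, field_strength = as.numeric(field_strength),
         subject_id = subject_id, sex = sex),
    class = "knee_slice"
  )
}

#' @export
print.knee_slice <- function(x, ...) {
  cat(sprintf("<knee_slice> %d x %d px, spacing %.3f x %.3f mm, thickness %.1f mm, index %d\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_spacing[1], x$pixel_spacing[2],
              x$slice_thickness, x$slice_index))
  invisible(x)
}

#' A subject's ordered slice stack with demographics
#'
#' @param subject_id Subject identifier.
#' @param age Decimal age in years at examination.
#' @param sex `"F"` or `"M"`.
#' @param slices List of [knee_slice] objects; must share pixel spacing and
#'   slice thickness (a consistency error otherwise). Stored sorted by
#'   `slice_index`.
#' @param device A [device_profile()].
#' @return Object of class `subject_study`.
#' @export
subject_study <- function(subject_id, age, sex, slices, device) {
  if (length(slices) < 1)
    stop_physari("a subject needs at least one slice", class = "physari_io_error")
  if (!all(vapply(slices, inherits, logical(1), "knee_slice")))
    stop_physari("slices must be knee_slice objects", class = "physari_validation_error")
  sp <- t(vapply(slices, function(s) s$pixel_spacing, numeric(2)))
  th <- vapply(slices, function(s) s$slice_thickness, numeric(1))
  if (nrow(unique(sp)) != 1 || length(unique(th)) != 1)
    stop_physari("slices differ in pixel spacing or slice thickness",
                 class = "physari_consistency_error")
  slices <- slices[order(vapply(slices, function(s) s$slice_index, integer(1)))]
  structure(
    list(subject_id = subject_id, age = as.numeric(age), sex = sex,
         slices = slices, device = device),
    class = "subject_study"
  )
}

#' @export
print.subject_study <- function(x, ...) {
  cat(sprintf("<subject_study> %s: %s, %.1f y, %d slices on %s\n",
              x$subject_id, x$sex, x$age, length(x$slices), x$device$name))
  invisible(x)
}

#' Physical area of one pixel
#'
#' The product of the row and column pixel spacings: the mm^2 covered by a
#' single pixel, the factor converting mask pixel counts to areas.
#'
#' @param slice A [knee_slice].
#' @return Area in mm^2 (strictly positive).
#' @examples
#' sl <- knee_slice(matrix(0L, 4, 4), c(0.5, 0.5), 4)
#' pixel_area(sl) # 0.25
#' @export
pixel_area <- function(slice) {
  stopifnot(inherits(slice, "knee_slice"))
  prod(slice$pixel_spacing)
}

# ---- minimal DICOM (Explicit VR Little Endian, monochrome) ----------------

dcm_u16 <- function(r, i) as.integer(r[i]) + 256L * as.integer(r[i + 1L])
dcm_u32 <- function(r, i) {
  as.integer(r[i]) + 256 * as.integer(r[i + 1L]) +
    65536 * as.integer(r[i + 2L]) + 16777216 * as.integer(r[i + 3L])
}

dcm_raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_str_payload <- function(s, pad = as.raw(0x20)) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, pad)
  r
}

dcm_ui_payload <- function(s) dcm_str_payload(s, pad = as.raw(0))

dcm_element <- function(group, element, vr, payload) {
  head <- c(dcm_raw_u16(group), dcm_raw_u16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), dcm_raw_u32(length(payload)), payload)
  } else {
    c(head, dcm_raw_u16(length(payload)), payload)
  }
}

dcm_ds <- function(x) paste(sprintf("%.10g", x), collapse = "\\")

#' Write one knee slice as a DICOM file
#'
#' Serializes a [knee_slice] as an uncompressed monochrome DICOM file
#' (Explicit VR Little Endian, 16 bits allocated / 12 stored) with the
#' metadata the morphometry reads back: Rows `[0028:0010]`, Columns
#' `[0028:0011]`, Pixel Spacing `[0028:0030]` as the standard
#' row\\column pair in mm, Slice Thickness `[0018:0050]` and Magnetic
#' Field Strength `[0018:0087]`. SOP instance UIDs are derived
#' deterministically from the subject id and instance number so identical
#' inputs produce bit-identical files.
#'
#' @param slice A [knee_slice]; pixel values must be integers in
#'   `[0, 65535]`.
#' @param path Output file path.
#' @param field_strength Tesla; defaults to the slice's stored value.
#' @param subject_id,sex Patient metadata; default to the slice's values.
#' @param instance_number DICOM Instance Number; defaults to
#'   `slice_index + 1`.
#' @return `path`, invisibly.
#' @seealso [read_slice()] for the matching reader.
#' @export
write_dicom_slice <- function(slice, path, field_strength = slice$field_strength,
                              subject_id = slice$subject_id, sex = slice$sex,
                              instance_number = slice$slice_index + 1L) {
  stopifnot(inherits(slice, "knee_slice"))
  px <- slice$pixels
  if (any(px < 0) || any(px > 65535) || any(px != round(px)))
    stop_physari("pixel values must be integers in [0, 65535] for DICOM output",
                 class = "physari_validation_error")
  if (is.na(subject_id)) subject_id <- "ANON"
  if (is.na(sex)) sex <- "O"
  if (is.na(field_strength)) field_strength <- 0

  uid_root <- "1.2.826.0.1.3680043.9999"
  sid_num <- suppressWarnings(as.numeric(gsub("\\D", "", subject_id)))
  if (!length(sid_num) || is.na(sid_num)) sid_num <- 0
  sop_class <- "1.2.840.10008.5.1.4.1.1.4" # MR Image Storage
  sop_uid <- sprintf("%s.%d.%d", uid_root, sid_num, as.integer(instance_number))

  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_element(0x0002, 0x0002, "UI", dcm_ui_payload(sop_class)),
    dcm_element(0x0002, 0x0003, "UI", dcm_ui_payload(sop_uid)),
    dcm_element(0x0002, 0x0010, "UI", dcm_ui_payload("1.2.840.10008.1.2.1")),
    dcm_element(0x0002, 0x0012, "UI", dcm_ui_payload(paste0(uid_root, ".1")))
  )
  pixel_payload <- writeBin(as.integer(t(px)), raw(), size = 2, endian = "little")
  body <- c(
    dcm_element(0x0008, 0x0016, "UI", dcm_ui_payload(sop_class)),
    dcm_element(0x0008, 0x0018, "UI", dcm_ui_payload(sop_uid)),
    dcm_element(0x0008, 0x0060, "CS", dcm_str_payload("MR")),
    dcm_element(0x0010, 0x0020, "LO", dcm_str_payload(subject_id)),
    dcm_element(0x0010, 0x0040, "CS", dcm_str_payload(sex)),
    dcm_element(0x0018, 0x0050, "DS", dcm_str_payload(dcm_ds(slice$slice_thickness))),
    dcm_element(0x0018, 0x0087, "DS", dcm_str_payload(dcm_ds(field_strength))),
    dcm_element(0x0020, 0x0013, "IS", dcm_str_payload(as.character(as.integer(instance_number)))),
    dcm_element(0x0028, 0x0002, "US", dcm_raw_u16(1)),
    dcm_element(0x0028, 0x0004, "CS", dcm_str_payload("MONOCHROME2")),
    dcm_element(0x0028, 0x0010, "US", dcm_raw_u16(nrow(px))),
    dcm_element(0x0028, 0x0011, "US", dcm_raw_u16(ncol(px))),
    dcm_element(0x0028, 0x0030, "DS", dcm_str_payload(dcm_ds(slice$pixel_spacing))),
    dcm_element(0x0028, 0x0100, "US", dcm_raw_u16(16)),
    dcm_element(0x0028, 0x0101, "US", dcm_raw_u16(12)),
    dcm_element(0x0028, 0x0102, "US", dcm_raw_u16(11)),
    dcm_element(0x0028, 0x0103, "US", dcm_raw_u16(0)),
    dcm_element(0x7FE0, 0x0010, "OW", pixel_payload)
  )
  out <- c(
    raw(128), charToRaw("DICM"),
    dcm_element(0x0002, 0x0000, "UL", dcm_raw_u32(length(meta))),
    meta, body
  )
  ok <- tryCatch({ writeBin(out, path); TRUE }, error = function(e) FALSE)
  if (!ok)
    stop_physari("cannot write DICOM file: ", path, class = "physari_io_error")
  invisible(path)
}

#' Read one knee slice from a DICOM file
#'
#' Parses an uncompressed Explicit VR Little Endian monochrome DICOM file
#' and returns the pixel grid together with the metadata the area formulas
#' consume: Pixel Spacing (returned in the stored row, column order),
#' Slice Thickness, Magnetic Field Strength and Instance Number (exposed
#' as the 0-based `slice_index`).
#'
#' @param path DICOM file path.
#' @return A [knee_slice].
#' @section Errors: A missing Pixel Spacing `[0028:0030]` or Slice
#'   Thickness `[0018:0050]` tag raises a metadata error naming the tag;
#'   unreadable or non-DICOM files raise an I/O error.
#' @export
read_slice <- function(path) {
  if (!file.exists(path))
    stop_physari("no such file: ", path, class = "physari_io_error")
  r <- readBin(path, "raw", file.size(path))
  if (length(r) < 132 || rawToChar(r[129:132]) != "DICM")
    stop_physari("not a DICOM file (missing DICM magic): ", path,
                 class = "physari_io_error")
  pos <- 133L
  tags <- list()
  pixel_raw <- NULL
  while (pos + 8L <= length(r) + 1L) {
    group <- dcm_u16(r, pos); element <- dcm_u16(r, pos + 2L)
    vr <- rawToChar(r[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- dcm_u32(r, pos + 8L); pos <- pos + 12L
    } else {
      len <- dcm_u16(r, pos + 6L); pos <- pos + 8L
    }
    val <- if (len > 0) r[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    key <- sprintf("%04X,%04X", group, element)
    if (group == 0x7FE0 && element == 0x0010) {
      pixel_raw <- val
      break
    }
    tags[[key]] <- list(vr = vr, val = val)
  }
  get_str <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    trimws(rawToChar(t$val[t$val != as.raw(0)]))
  }
  get_us <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    dcm_u16(t$val, 1L)
  }
  ts <- get_str("0002,0010")
  if (!is.null(ts) && ts != "1.2.840.10008.1.2.1")
    stop_physari("unsupported transfer syntax: ", ts, class = "physari_io_error")
  spacing_s <- get_str("0028,0030")
  if (is.null(spacing_s))
    stop_physari("missing DICOM tag [0028:0030] Pixel Spacing in ", path,
                 class = "physari_metadata_error")
  thickness_s <- get_str("0018,0050")
  if (is.null(thickness_s))
    stop_physari("missing DICOM tag [0018:0050] Slice Thickness in ", path,
                 class = "physari_metadata_error")
  rows <- get_us("0028,0010"); cols <- get_us("0028,0011")
  if (is.null(rows) || is.null(cols) || is.null(pixel_raw))
    stop_physari("missing image dimensions or pixel data in ", path,
                 class = "physari_metadata_error")
  spacing <- as.numeric(strsplit(spacing_s, "\\", fixed = TRUE)[[1]])
  if (length(spacing) == 1) spacing <- rep(spacing, 2)
  px <- readBin(pixel_raw, "integer", n = rows * cols, size = 2,
                endian = "little", signed = FALSE)
  instance <- get_str("0020,0013")
  field_s <- get_str("0018,0087")
  knee_slice(
    pixels = matrix(px, nrow = rows, ncol = cols, byrow = TRUE),
    pixel_spacing = spacing,
    slice_thickness = as.numeric(thickness_s),
    slice_index = if (is.null(instance)) 0L else as.integer(instance) - 1L,
    source_path = path,
    field_strength = if (is.null(field_s)) NA_real_ else as.numeric(field_s),
    subject_id = if (is.null(get_str("0010,0020"))) NA_character_ else get_str("0010,0020"),
    sex = if (is.null(get_str("0010,0040"))) NA_character_ else get_str("0010,0040")
  )
}

#' Write a synthetic cohort as per-subject DICOM series
#'
#' One DICOM file per slice under `directory/<subject_id>/`, plus a
#' `metadata.csv` table (subject_id, age, sex, device) in `directory`.
#' Re-reading any file with [read_slice()] reproduces its pixel grid and
#' geometry tags exactly.
#'
#' @param cohort List of subjects as returned by [generate_cohort()] (or a
#'   list of bare `subject_study` objects).
#' @param directory Output directory (created if absent).
#' @return Invisible manifest data frame (subject_id, slice_index, path);
#'   empty for an empty cohort, in which case no files are written.
#' @export
write_cohort_dicom <- function(cohort, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory))
    stop_physari("cannot create directory: ", directory, class = "physari_io_error")
  manifest <- data.frame(subject_id = character(), slice_index = integer(),
                         path = character(), stringsAsFactors = FALSE)
  meta <- data.frame(subject_id = character(), age = numeric(), sex = character(),
                     device = character(), stringsAsFactors = FALSE)
  for (subj in cohort) {
    study <- if (inherits(subj, "subject_study")) subj else subj$study
    sdir <- file.path(directory, study$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    for (sl in study$slices) {
      p <- file.path(sdir, sprintf("%s_%03d.dcm", study$subject_id, sl$slice_index))
      write_dicom_slice(sl, p, field_strength = study$device$field_strength,
                        subject_id = study$subject_id, sex = study$sex)
      manifest <- rbind(manifest, data.frame(
        subject_id = study$subject_id, slice_index = sl$slice_index, path = p,
        stringsAsFactors = FALSE))
    }
    meta <- rbind(meta, data.frame(
      subject_id = study$subject_id, age = study$age, sex = study$sex,
      device = study$device$name, stringsAsFactors = FALSE))
  }
  if (nrow(meta) > 0)
    write.csv(meta, file.path(directory, "metadata.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Load a subject's DICOM series from a directory
#'
#' Reads every `.dcm` file in `directory`, orders slices by their stored
#' instance number, enforces contiguous indices and homogeneous geometry
#' (identical pixel spacing and slice thickness across the stack), and
#' attaches demographics from `metadata_record`.
#'
#' @param directory Directory holding one subject's DICOM slices.
#' @param metadata_record List or one-row data frame with `subject_id`,
#'   `sex`, `device` (a name or a [device_profile()]) and either `age`
#'   (decimal years) or `birth_date` and `exam_date` (coercible to Date),
#'   in which case age is computed as the date difference over 365.25.
#' @return A [subject_study()].
#' @export
load_subject <- function(directory, metadata_record) {
  files <- list.files(directory, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0)
    stop_physari("no DICOM files in ", directory, class = "physari_io_error")
  md <- as.list(metadata_record)
  slices <- lapply(sort(files), read_slice)
  idx <- sort(vapply(slices, function(s) s$slice_index, integer(1)))
  if (!identical(idx, seq(min(idx), length.out = length(idx))))
    stop_physari("slice indices are not contiguous after sorting",
                 class = "physari_consistency_error")
  age <- if (!is.null(md$birth_date) && !is.null(md$exam_date)) {
    as.numeric(as.Date(md$exam_date) - as.Date(md$birth_date)) / 365.25
  } else md$age
  if (is.null(age))
    stop_physari("metadata_record needs age or birth/exam dates",
                 class = "physari_metadata_error")
  dev <- md$device
  if (!inherits(dev, "device_profile")) {
    s1 <- slices[[1]]
    dev <- device_profile(
      name = if (is.null(dev)) "unknown" else as.character(dev),
      field_strength = if (is.na(s1$field_strength) || s1$field_strength <= 0) 1.5
                       else s1$field_strength,
      pixel_spacing = s1$pixel_spacing,
      matrix_size = dim(s1$pixels),
      slice_thickness = s1$slice_thickness
    )
  }
  subject_study(
    subject_id = if (is.null(md$subject_id)) slices[[1]]$subject_id else md$subject_id,
    age = age, sex = md$sex, slices = slices, device = dev
  )
}
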