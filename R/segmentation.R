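#' Intensity range for thresholding
#'
#' The boundary condition of range thresholding: pixels with intensity in
#' `[t_min, t_max]` (inclusive at both ends) are kept.
#'
#' @param t_min,t_max Lower and upper intensity bounds, `t_min <= t_max`.
#' @return Object of class `threshold_spec`.
#' @export
threshold_spec <- function(t_min, t_max) {
  if (!is.finite(t_min) || !is.finite(t_max) || t_min > t_max)
    stop_physari("threshold_spec requires finite t_min <= t_max",
                 class = "physari_validation_error")
  structure(list(t_min = as.numeric(t_min), t_max = as.numeric(t_max)),
            class = "threshold_spec")
}

#' Rectangular region of interest
#'
#' A 0-based, half-open rectangle `(top, left, height, width)` in
#' (row, col) order: rows `top .. top + height - 1`.
#'
#' @param top,left 0-based offsets of the top-left pixel.
#' @param height,width Extent in pixels (>= 1).
#' @return Object of class `bounding_box`.
#' @export
bounding_box <- function(top, left, height, width) {
  if (any(c(top, left) < 0) || any(c(height, width) < 1))
    stop_physari("bounding_box needs top, left >= 0 and height, width >= 1",
                 class = "physari_validation_error")
  structure(list(top = as.integer(top), left = as.integer(left),
                 height = as.integer(height), width = as.integer(width)),
            class = "bounding_box")
}

#' Default ROI: a fixed central window
#'
#' The anatomy of interest (plate band and the femur just below it) sits at
#' the image centre on coronal knee series, so one fixed central window
#' serves a whole cohort. When pixel spacing is known (a [knee_slice], or
#' `spacing` given) the window covers a fixed physical extent
#' (`extent_mm`, default 70 mm -- roughly the central 50% of a typical
#' 140--160 mm knee field of view), so the same anatomy is cropped
#' regardless of the acquisition matrix and pixel size. For a bare matrix
#' with unknown spacing it falls back to the central 50% x 50% pixel
#' window. Override per cohort via the pipeline config when acquisitions
#' are framed differently.
#'
#' @param dims Image dimensions `(rows, cols)` or a [knee_slice].
#' @param spacing Optional `(row, col)` pixel spacing in mm.
#' @param extent_mm Physical window size in mm.
#' @return A [bounding_box()].
#' @export
default_roi_box <- function(dims, spacing = NULL, extent_mm = 70) {
  if (inherits(dims, "knee_slice")) {
    spacing <- dims$pixel_spacing
    dims <- dim(dims$pixels)
  }
  if (is.null(spacing)) {
    half <- floor(dims / 4)
  } else {
    half <- pmin(floor(extent_mm / 2 / spacing), floor(dims / 4) * 2 - 1)
  }
  bounding_box(top = floor(dims[1] / 2) - half[1], left = floor(dims[2] / 2) - half[2],
               height = 2 * half[1], width = 2 * half[2])
}

#' Crop a slice (or matrix) to a bounding box
#'
#' @param x A [knee_slice] or a matrix.
#' @param box A [bounding_box()]; must lie inside the image.
#' @return The sub-image (matrix) with the box recorded in attribute
#'   `"box"` so masks can later be re-embedded in full-frame coordinates.
#' @export
crop_roi <- function(x, box) {
  img <- if (inherits(x, "knee_slice")) x$pixels else x
  stopifnot(inherits(box, "bounding_box"))
  if (box$top + box$height > nrow(img) || box$left + box$width > ncol(img))
    stop_physari("bounding box exceeds image bounds",
                 class = "physari_validation_error")
  patch <- img[(box$top + 1L):(box$top + box$height),
               (box$left + 1L):(box$left + box$width), drop = FALSE]
  attr(patch, "box") <- box
  patch
}

#' 8-connected component labeling of a binary mask
#'
#' Labels connected foreground components using 8-connectivity (diagonal
#' neighbors connect), the convention of MATLAB's `bwlabel` default and the
#' appropriate one for thin, near-diagonal structures such as a one-pixel
#' plate band: under 4-connectivity a staircase line falls apart into short
#' runs. Implemented as run-length union-find over row runs.
#'
#' @param mask Binary matrix.
#' @return Integer matrix of component labels (0 = background), with the
#'   number of components as attribute `"n"`.
#' @export
label_components <- function(mask) {
  m <- as_binary_mask(mask)
  nr <- nrow(m); nc <- ncol(m)
  runs_row <- integer(0); runs_s <- integer(0); runs_e <- integer(0)
  for (r in seq_len(nr)) {
    v <- m[r, ]
    if (!any(v == 1L)) next
    rl <- rle(v)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    sel <- rl$values == 1L
    runs_row <- c(runs_row, rep(r, sum(sel)))
    runs_s <- c(runs_s, starts[sel]); runs_e <- c(runs_e, ends[sel])
  }
  n <- length(runs_row)
  out <- matrix(0L, nr, nc)
  if (n == 0) { attr(out, "n") <- 0L; return(out) }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  prev <- integer(0)
  for (r in sort(unique(runs_row))) {
    cur <- which(runs_row == r)
    if (length(prev) > 0 && runs_row[prev[1]] == r - 1L) {
      for (i in cur) for (j in prev) {
        if (runs_s[i] <= runs_e[j] + 1L && runs_e[i] >= runs_s[j] - 1L) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
    prev <- cur
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- match(roots, unique(roots))
  for (i in seq_len(n)) out[runs_row[i], runs_s[i]:runs_e[i]] <- labels[i]
  attr(out, "n") <- length(unique(roots))
  out
}

# Re-embed an ROI mask into full-frame coordinates (zeros outside the box).
embed_roi <- function(mask, box, dims) {
  full <- matrix(0L, dims[1], dims[2])
  full[(box$top + 1L):(box$top + box$height),
       (box$left + 1L):(box$left + box$width)] <- mask
  full
}

#' Range thresholding of a grayscale image
#'
#' The output is a binary image with 1 wherever the input intensity lies
#' within the preserved range `[t_min, t_max]` (inclusive) and 0 otherwise.
#'
#' @param image Non-empty numeric matrix.
#' @param spec A [threshold_spec()].
#' @return Integer 0/1 matrix of the same shape.
#' @examples
#' threshold_segment(matrix(c(1, 9, 5, 3), 2, 2), threshold_spec(2, 6))
#' @export
threshold_segment <- function(image, spec) {
  if (!is.matrix(image) || length(image) == 0)
    stop_physari("image must be a non-empty matrix", class = "physari_validation_error")
  stopifnot(inherits(spec, "threshold_spec"))
  as_binary_mask(image >= spec$t_min & image <= spec$t_max)
}

#' Refinement parameters for binary plate masks
#'
#' @param median Logical: median-filter (3 x 3) the ROI before
#'   thresholding. Applied by [segment_growth_plate()], not by
#'   [refine_mask()] itself, since it acts on intensities. Off by default:
#'   at the default noise level thresholding plus closing and the size
#'   filter already clean the mask, while a 3 x 3 median erodes the
#'   right-angle corners at the ends of thin plate bands; enable it for
#'   substantially noisier data.
#' @param close_radius Radius (px) of the elliptical structuring element
#'   used for binary closing; 0 (the default) disables closing. With
#'   8-connected component filtering a thin plate band already survives as
#'   one component, and closing a cleanly thresholded band is not a no-op:
#'   wherever the wavy boundary's extremum grazes a pixel row it leaves a
#'   one-deep, two-wide notch that a 3 x 3 closing fills. Enable closing
#'   for data with enough noise to punch holes in the band.
#' @param min_component Connected components smaller than this pixel count
#'   are removed.
#' @param keep_largest Logical: keep only the largest component.
#' @return List of class `refine_params`.
#' @export
refine_params <- function(median = FALSE, close_radius = 0, min_component = 20,
                          keep_largest = FALSE) {
  structure(list(median = isTRUE(median), close_radius = as.integer(close_radius),
                 min_component = as.integer(min_component),
                 keep_largest = isTRUE(keep_largest)),
            class = "refine_params")
}

#' Morphological refinement of a binary mask
#'
#' Applies, in order: binary closing with an elliptical (disc) structuring
#' element of radius `close_radius`, removal of connected components
#' (8-connected, see [label_components()]) smaller than `min_component`
#' pixels, and optionally keeping only the largest component. The output is
#' binary and confined to the input domain's shape.
#'
#' @param mask Binary matrix.
#' @param params A [refine_params()].
#' @return Integer 0/1 matrix of the same shape.
#' @export
refine_mask <- function(mask, params = refine_params()) {
  m <- as_binary_mask(mask)
  if (sum(m) == 0) return(m)
  if (params$close_radius > 0) {
    brush <- EBImage::makeBrush(2L * params$close_radius + 1L, shape = "disc")
    m <- as_binary_mask(EBImage::closing(m, brush))
  }
  if (params$min_component > 0 || params$keep_largest) {
    lbl <- label_components(m)
    nlab <- max(lbl)
    if (nlab > 0) {
      sizes <- tabulate(lbl[lbl > 0], nbins = nlab)
      keep <- sizes >= params$min_component
      if (params$keep_largest) keep <- keep & sizes == max(sizes)
      m <- as_binary_mask(matrix(lbl %in% which(keep), nrow(m), ncol(m)))
    }
  }
  m
}

#' Data-driven threshold range for the dark plate band
#'
#' The plate appears as a dark band against bright bone, so a bimodal ROI
#' histogram separates the two. The preserved range is
#' `[min(ROI), alpha * T_otsu]`, where `T_otsu` is the Otsu split of the
#' ROI histogram and `alpha < 1` pulls the upper bound toward the dark
#' mode, selecting the dark-line class while rejecting bone.
#'
#' @param roi Numeric matrix with at least two distinct intensities.
#' @param otsu_fraction `alpha`, default 0.6.
#' @return A [threshold_spec()].
#' @export
auto_threshold <- function(roi, otsu_fraction = 0.6) {
  if (!is.matrix(roi) || length(roi) == 0)
    stop_physari("roi must be a non-empty matrix", class = "physari_validation_error")
  mn <- min(roi); mx <- max(roi)
  if (mx <= mn)
    stop_physari("cannot auto-threshold a constant image",
                 class = "physari_validation_error")
  t_otsu <- mn + (mx - mn) *
    EBImage::otsu((roi - mn) / (mx - mn), range = c(0, 1), levels = 256)
  threshold_spec(mn, otsu_fraction * t_otsu)
}

#' Semi-automatic growth-plate segmentation of one slice
#'
#' The composition crop -> (optional 3 x 3 median filter) -> range
#' threshold -> morphological refinement -> re-embedding into full-frame
#' coordinates with zeros outside the box. With `spec = NULL` the threshold
#' range is chosen from the ROI histogram by [auto_threshold()].
#'
#' @param slice A [knee_slice] (or bare matrix).
#' @param box A [bounding_box()]; default the central 50% window.
#' @param spec A [threshold_spec()] or `NULL` for automatic selection.
#' @param refine A [refine_params()].
#' @param otsu_fraction Passed to [auto_threshold()] when `spec` is `NULL`.
#' @return Full-frame integer 0/1 plate mask.
#' @export
segment_growth_plate <- function(slice, box = NULL, spec = NULL,
                                 refine = refine_params(), otsu_fraction = 0.6) {
  img <- if (inherits(slice, "knee_slice")) slice$pixels else slice
  if (is.null(box)) {
    box <- if (inherits(slice, "knee_slice")) default_roi_box(slice) else
      default_roi_box(dim(img))
  }
  roi <- crop_roi(img, box)
  if (refine$median) {
    mx <- max(roi, 1)
    roi_f <- round(EBImage::medianFilter(roi / mx, size = 1) * mx)
  } else {
    roi_f <- roi
  }
  if (is.null(spec)) spec <- auto_threshold(roi_f, otsu_fraction)
  m <- threshold_segment(roi_f, spec)
  m <- refine_mask(m, refine)
  embed_roi(m, box, dim(img))
}

#' Load a manually segmented femur mask from a lossless image file
#'
#' Ingests the manual-segmentation step's output: a single-channel PNG
#' (0/255 or any coding where positive means foreground) whose shape must
#' match the slice.
#'
#' @param path PNG file path.
#' @param slice The [knee_slice] the mask belongs to.
#' @return Integer 0/1 matrix.
#' @export
load_femur_mask <- function(path, slice) {
  if (!file.exists(path))
    stop_physari("no such mask file: ", path, class = "physari_io_error")
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  if (!all(dim(img) == dim(slice$pixels)))
    stop_physari(sprintf("mask shape %d x %d does not match slice %d x %d",
                         nrow(img), ncol(img), nrow(slice$pixels), ncol(slice$pixels)),
                 class = "physari_consistency_error")
  as_binary_mask(img > 0)
}

#' Write a binary mask as a lossless PNG (0/255)
#'
#' @param mask Binary matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(as_binary_mask(mask) * 1.0, path)
  invisible(path)
}

#' Is the growth plate visible on this slice?
#'
#' Only slices where the plate is clearly visible enter the per-subject
#' sums; visibility is operationalized as a minimum positive-pixel count.
#'
#' @param plate_mask Binary matrix.
#' @param min_pixels Visibility threshold (default 20).
#' @return Logical.
#' @export
is_plate_visible <- function(plate_mask, min_pixels = 20) {
  sum(as_binary_mask(plate_mask)) >= min_pixels
}

#' Burn a mask outline into the original image
#'
#' Overlays the morphological boundary of `plate_mask` (mask minus its
#' erosion) on the slice at maximum intensity, for visual QC of the
#' segmentation.
#'
#' @param slice A [knee_slice] or matrix.
#' @param plate_mask Binary matrix of the same shape.
#' @return Numeric matrix; write with [write_mask_png()]-style scaling or
#'   `png::writePNG(x / max(x))`.
#' @export
outline_overlay <- function(slice, plate_mask) {
  img <- if (inherits(slice, "knee_slice")) slice$pixels else slice
  m <- as_binary_mask(plate_mask)
  if (!all(dim(m) == dim(img)))
    stop_physari("mask shape does not match slice", class = "physari_consistency_error")
  if (sum(m) == 0) return(img)
  # pad with background so erosion also shrinks at the image border
  padded <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
  padded[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  er <- as_binary_mask(EBImage::erode(padded, EBImage::makeBrush(3, "box")))
  er <- er[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)]
  boundary <- m == 1L & er == 0L
  out <- img
  out[boundary] <- max(img)
  out
}
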