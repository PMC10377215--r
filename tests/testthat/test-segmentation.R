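test_that("range thresholding equals the exhaustive per-pixel oracle", {
  spec <- threshold_spec(2, 6)
  expect_identical(threshold_segment(matrix(c(1, 9, 5, 3), 2, 2, byrow = TRUE), spec),
                   matrix(c(0L, 0L, 1L, 1L), 2, 2, byrow = TRUE))
  img <- matrix(1:12, 3, 4)
  expect_identical(threshold_segment(img, threshold_spec(min(img), max(img))),
                   matrix(1L, 3, 4))
  set.seed(42)
  for (i in 1:25) {
    img <- matrix(sample.int(255, 64 * 64, replace = TRUE), 64, 64)
    b <- sort(sample.int(255, 2))
    expect_identical(threshold_segment(img, threshold_spec(b[1], b[2])),
                     oracle_threshold(img, b[1], b[2]))
  }
  expect_error(threshold_spec(6, 2), class = "physari_validation_error")
})

test_that("cropping respects bounds and records the box", {
  img <- matrix(1:(320 * 320), 320, 320)
  full <- crop_roi(img, bounding_box(0, 0, 320, 320))
  expect_equal(full, img, ignore_attr = TRUE)
  patch <- crop_roi(img, bounding_box(80, 80, 160, 160))
  expect_equal(dim(patch), c(160, 160))
  expect_equal(patch[1, 1], img[81, 81])
  expect_error(crop_roi(img, bounding_box(200, 200, 160, 160)),
               class = "physari_validation_error")
  expect_error(bounding_box(-1, 0, 10, 10), class = "physari_validation_error")
})

test_that("component labeling is 8-connected and matches a BFS oracle", {
  diag8 <- matrix(0L, 8, 8); for (i in 1:8) diag8[i, i] <- 1L
  expect_equal(attr(label_components(diag8), "n"), 1)
  two <- matrix(0L, 10, 10); two[1:2, 1:2] <- 1L; two[7:9, 7:8] <- 1L
  lbl <- label_components(two)
  expect_equal(attr(lbl, "n"), 2)
  expect_equal(sort(tabulate(lbl[lbl > 0])), c(4, 6))
  set.seed(7)
  for (i in 1:20) {
    m <- matrix(as.integer(runif(20 * 20) < 0.35), 20, 20)
    expect_equal(attr(label_components(m), "n"), oracle_components8(m))
  }
})

test_that("mask refinement removes specks, keeps bands, and is idempotent", {
  m <- matrix(0L, 60, 60)
  m[30:34, 5:55] <- 1L                  # a 255-px band
  m[c(3, 10), c(3, 50)] <- 1L           # 2-px specks (4 singletons)
  m[50, 10:11] <- 1L                    # one 2-px speck
  r <- refine_mask(m, refine_params(close_radius = 0, min_component = 20))
  expect_equal(sum(r), 5 * 51)
  expect_true(all(r[30:34, 5:55] == 1L))
  expect_identical(refine_mask(r, refine_params(close_radius = 0, min_component = 20)), r)
  expect_identical(refine_mask(matrix(0L, 10, 10)), matrix(0L, 10, 10))
  # keep-largest retains only the biggest component
  two <- matrix(0L, 40, 40); two[5:10, 5:10] <- 1L; two[25:35, 25:35] <- 1L
  kl <- refine_mask(two, refine_params(min_component = 0, keep_largest = TRUE))
  expect_equal(sum(kl), 11 * 11)
})

test_that("auto threshold brackets the dark mode of a bimodal ROI", {
  roi <- matrix(c(rep(40, 200), rep(200, 824)), 32, 32)
  spec <- auto_threshold(roi)
  expect_equal(spec$t_min, 40)
  expect_gt(spec$t_max, 40)
  expect_lt(spec$t_max, 200)
  expect_error(auto_threshold(matrix(5, 8, 8)), class = "physari_validation_error")
})

test_that("noise-free phantoms are recovered exactly by the full chain", {
  # at the 0.5 mm test resolution the band stays >= 2 px per column up to
  # age ~16; thinner bands are exercised on the clinical devices elsewhere
  for (age in c(10, 16)) {
    ph <- test_phantom(age = age, noise_sd = 0, seed = age)
    for (s in seq_along(ph$study$slices)) {
      m <- segment_growth_plate(ph$study$slices[[s]])
      expect_identical(m, ph$truth$plate_masks[[s]])
    }
  }
})

test_that("refinement is a no-op on clean phantom plate masks", {
  ph <- test_phantom(age = 10, noise_sd = 0, seed = 9)
  for (s in seq_along(ph$study$slices)) {
    truth <- ph$truth$plate_masks[[s]]
    expect_identical(refine_mask(truth, refine_params()), truth)
  }
})

test_that("segmentation output is confined to the bounding box", {
  ph <- test_phantom(age = 12, noise_sd = 10, seed = 12)
  sl <- ph$study$slices[[1]]
  box <- bounding_box(40, 30, 50, 60)
  m <- segment_growth_plate(sl, box = box)
  outside <- m
  outside[(box$top + 1):(box$top + box$height),
          (box$left + 1):(box$left + box$width)] <- 0L
  expect_equal(sum(outside), 0)
  # a range excluding every intensity present yields an empty mask
  empty <- segment_growth_plate(sl, spec = threshold_spec(-10, -1))
  expect_equal(sum(empty), 0)
})

test_that("noisy phantoms are segmented with high overlap (Dice >= 0.90)", {
  for (seed in c(6, 16)) {
    ph <- test_phantom(age = 10, noise_sd = 10, seed = seed)
    for (s in seq_along(ph$study$slices)) {
      m <- segment_growth_plate(ph$study$slices[[s]])
      truth <- ph$truth$plate_masks[[s]]
      dice <- 2 * sum(m & truth) / (sum(m) + sum(truth))
      expect_gte(dice, 0.90)
    }
  }
})

test_that("median pre-filtering still yields high-overlap masks on noisy input", {
  ph <- test_phantom(age = 10, noise_sd = 15, seed = 26)
  m <- segment_growth_plate(ph$study$slices[[1]],
                            refine = refine_params(median = TRUE))
  truth <- ph$truth$plate_masks[[1]]
  expect_gte(2 * sum(m & truth) / (sum(m) + sum(truth)), 0.90)
})

test_that("femur masks round-trip through PNG and shape mismatches are caught", {
  ph <- test_phantom(age = 12, noise_sd = 0, seed = 14, n_slices = 1)
  sl <- ph$study$slices[[1]]
  truth <- ph$truth$femur_masks[[1]]
  f <- withr::local_tempfile(fileext = ".png")
  write_mask_png(truth, f)
  back <- load_femur_mask(f, sl)
  expect_identical(back, truth)

  zero <- withr::local_tempfile(fileext = ".png")
  write_mask_png(matrix(0L, nrow(truth), ncol(truth)), zero)
  expect_equal(sum(load_femur_mask(zero, sl)), 0)

  small <- withr::local_tempfile(fileext = ".png")
  write_mask_png(matrix(1L, 10, 10), small)
  expect_error(load_femur_mask(small, sl), class = "physari_consistency_error")
})

test_that("plate visibility rule counts positive pixels", {
  expect_false(is_plate_visible(matrix(0L, 10, 10)))
  m <- matrix(0L, 10, 10); m[1:4, 1:5] <- 1L
  expect_true(is_plate_visible(m, min_pixels = 20))
  expect_false(is_plate_visible(m, min_pixels = 21))
  # default phantoms keep the plate visible on every slice across the age
  # range, even on the coarsest study device (Panorama)
  for (age in c(10, 18, 26)) {
    ph <- generate_subject(phantom_spec(age = age, sex = "F",
                                        device = knee_mri_devices()$panorama,
                                        n_slices = 7, noise_sd = 10, seed = age))
    for (s in seq_along(ph$study$slices))
      expect_true(is_plate_visible(segment_growth_plate(ph$study$slices[[s]])))
  }
})

test_that("outline overlay burns only the mask boundary into the image", {
  ph <- test_phantom(age = 12, noise_sd = 0, seed = 17, n_slices = 1)
  sl <- ph$study$slices[[1]]
  plate <- ph$truth$plate_masks[[1]]
  expect_identical(outline_overlay(sl, matrix(0L, nrow(plate), ncol(plate))),
                   sl$pixels)
  ov <- outline_overlay(sl, plate)
  changed <- which(ov != sl$pixels)
  expect_gt(length(changed), 0)
  expect_true(all(plate[changed] == 1L))  # boundary is a subset of the mask
  img <- matrix(0, 8, 8); img[4, 4] <- 9
  ring <- outline_overlay(img, matrix(1L, 8, 8))
  expect_equal(sum(ring == 9), 8 * 8 - 6 * 6 + 1)  # border ring + the original max
  expect_equal(sum(ring[2:7, 2:7] == 9), 1)
})
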