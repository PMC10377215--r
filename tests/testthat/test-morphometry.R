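test_that("mask areas equal pixel count times pixel area (brute-force oracle)", {
  m <- matrix(0L, 20, 20); m[1:10, 1:10] <- 1L
  expect_equal(mask_area(m, 0.25), list(n_pix = 100, area = 25))
  expect_equal(mask_area(matrix(0L, 5, 5), 0.3), list(n_pix = 0, area = 0))
  set.seed(3)
  for (i in 1:10) {
    m <- matrix(as.integer(runif(30 * 30) < 0.4), 30, 30)
    pa <- runif(1, 0.05, 1)
    res <- mask_area(m, pa)
    expect_equal(res$n_pix, oracle_count(m))
    expect_equal(res$area, pa * oracle_count(m))
  }
  expect_error(mask_area(m, 0), class = "physari_validation_error")
})

test_that("subject totals sum slice areas and are order-invariant", {
  ps <- data.frame(A_sf = c(10, 20, 30), A_se = c(1, 2, 3))
  expect_equal(subject_totals(ps), list(Af = 60, Ae = 6))
  expect_equal(subject_totals(ps[c(3, 1, 2), ]), list(Af = 60, Ae = 6))
  expect_equal(subject_totals(ps[2, , drop = FALSE]), list(Af = 20, Ae = 2))
  expect_error(subject_totals(ps[0, ]), class = "physari_validation_error")
})

test_that("ARI and VRI definitions, the fused-plate error, and their identity", {
  expect_equal(compute_ari(150, 15), 10)
  expect_equal(compute_ari(0, 5), 0)
  expect_error(compute_ari(10, 0), class = "physari_fused_plate_error")
  expect_error(compute_vri(10, 0), class = "physari_fused_plate_error")

  expect_equal(compute_volumes(60, 6, Ts = 4, Ns = 3), list(Vf = 720, Ve = 72))
  expect_equal(compute_volumes(60, 6, Ts = 4, Ns = 1)$Vf, 240)
  expect_equal(compute_volumes(60, 6, Ts = 4, Ns = 3, mode = "slab"),
               list(Vf = 240, Ve = 24))
  v <- compute_volumes(60, 6, Ts = 4, Ns = 3)
  expect_identical(compute_vri(v$Vf, v$Ve), compute_ari(60, 6))

  # the identity holds for arbitrary positive inputs and either volume
  # convention (the common factor cancels; division of the rounded volumes
  # agrees to machine precision)
  set.seed(8)
  for (i in 1:200) {
    Af <- runif(1, 1, 5000); Ae <- runif(1, 0.1, 500)
    Ts <- runif(1, 1, 6); Ns <- sample.int(9, 1)
    mode <- sample(c("as-printed", "slab"), 1)
    v <- compute_volumes(Af, Ae, Ts, Ns, mode = mode)
    expect_equal(compute_vri(v$Vf, v$Ve), compute_ari(Af, Ae), tolerance = 1e-12)
  }
})

test_that("measure_subject reproduces the nominal ARI from truth masks", {
  ph <- test_phantom(age = 13, noise_sd = 0, seed = 19)
  seg <- segmentation_result("truth", ph$truth$femur_masks, ph$truth$plate_masks)
  m <- measure_subject(ph$study, seg)
  expect_identical(m$ARI, ph$truth$nominal_ARI)
  expect_identical(m$VRI, m$ARI)
  expect_equal(m$Ns, length(ph$study$slices))
  expect_equal(m$Af, sum(m$per_slice$A_sf))
  expect_equal(m$Ae, sum(m$per_slice$A_se))
  expect_equal(m$Vf, m$Af * m$Ts * m$Ns)
  # areas follow A = pix_area x N exactly
  pa <- pixel_area(ph$study$slices[[1]])
  expect_equal(m$per_slice$A_se, pa * m$per_slice$N_pix_e)
})

test_that("identical observer masks give identical morphometry", {
  ph <- test_phantom(age = 13, noise_sd = 0, seed = 23)
  obs <- simulate_observer_masks(ph$truth, perturbation = 0, seed = 1,
                                 n_observers = 2)
  m1 <- measure_subject(ph$study, segmentation_result("Obs1", obs[[1]]$femur_masks,
                                                      ph$truth$plate_masks))
  m2 <- measure_subject(ph$study, segmentation_result("Obs2", obs[[2]]$femur_masks,
                                                      ph$truth$plate_masks))
  expect_identical(m1$ARI, m2$ARI)
  expect_identical(m1$per_slice, m2$per_slice)
})

test_that("invisible slices are excluded from both sums", {
  ph <- test_phantom(age = 13, noise_sd = 0, seed = 29, n_slices = 4)
  plates <- ph$truth$plate_masks
  blank <- plates
  blank[[2]] <- matrix(0L, nrow(plates[[2]]), ncol(plates[[2]]))
  seg_full <- segmentation_result("o", ph$truth$femur_masks, plates)
  seg_blank <- segmentation_result("o", ph$truth$femur_masks, blank)
  m_full <- measure_subject(ph$study, seg_full)
  m_blank <- measure_subject(ph$study, seg_blank)
  expect_equal(m_blank$Ns, 3)
  # manual exclusion of slice 2 from the full measurement matches
  keep <- m_full$per_slice$slice_index != 1L
  expect_equal(m_blank$Af, sum(m_full$per_slice$A_sf[keep]))
  expect_equal(m_blank$ARI,
               sum(m_full$per_slice$A_sf[keep]) / sum(m_full$per_slice$A_se[keep]))

  all_blank <- lapply(plates, function(p) matrix(0L, nrow(p), ncol(p)))
  expect_error(measure_subject(ph$study,
                               segmentation_result("o", ph$truth$femur_masks, all_blank)),
               class = "physari_validation_error")
})

test_that("femur/plate overlap is resolved in favor of the plate", {
  sl <- knee_slice(matrix(100L, 10, 10), c(1, 1), 4)
  st <- subject_study("S", 12, "F", list(sl), test_device())
  femur <- matrix(0L, 10, 10); femur[4:9, ] <- 1L
  plate <- matrix(0L, 10, 10); plate[3:4, 2:9] <- 1L  # row 4 overlaps the femur
  m <- measure_subject(st, segmentation_result("o", list(femur), list(plate)),
                       visibility_min = 1)
  expect_equal(m$per_slice$N_pix_e, sum(plate))
  expect_equal(m$per_slice$N_pix_f, sum(femur) - 8)  # overlap removed from femur
})

test_that("areas scale with pixel spacing but ARI does not", {
  base <- matrix(0L, 12, 12); base[7:10, 2:11] <- 1L
  plate <- matrix(0L, 12, 12); plate[5:6, 3:10] <- 1L
  for (sp in list(c(0.5, 0.5), c(1, 1))) {
    sl <- knee_slice(matrix(100L, 12, 12), sp, 4)
    st <- subject_study("S", 12, "F", list(sl), test_device(spacing = sp[1]))
    m <- measure_subject(st, segmentation_result("o", list(base), list(plate)),
                         visibility_min = 1)
    if (sp[1] == 0.5) a_small <- m
  }
  expect_equal(m$Af, a_small$Af * 4)
  expect_equal(m$Ae, a_small$Ae * 4)
  expect_identical(m$ARI, a_small$ARI)
})

test_that("the same phantom at extreme pixel sizes yields nearly identical ARI", {
  ari <- sapply(c(0.273, 0.625), function(px) {
    n <- if (px < 0.5) 512L else 288L
    ph <- generate_subject(phantom_spec(age = 14, sex = "F",
                                        device = device_profile("d", 1.5, px, c(n, n), 4),
                                        n_slices = 3, noise_sd = 0, seed = 33))
    seg <- segmentation_result("o", ph$truth$femur_masks, ph$truth$plate_masks)
    measure_subject(ph$study, seg)$ARI
  })
  expect_lt(abs(ari[1] - ari[2]) / ari[1], 0.05)
})
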