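test_that("background estimation reports mean/sd/count and enforces ROI size", {
  vol <- volume_grid(array(1.2, c(10, 10, 10)), spacing = c(2, 2, 2))
  roi <- fet_mask(array(rep(c(1L, 0L), c(500, 500)), c(10, 10, 10)),
                  reference = vol, label = "background_roi")
  bg <- estimate_background(vol, roi)
  expect_equal(bg$mean_suv, 1.2)
  expect_equal(bg$sd_suv, 0)
  expect_equal(bg$n_voxels, 500)

  small <- fet_mask(array(rep(c(1L, 0L), c(50, 950)), c(10, 10, 10)),
                    reference = vol)
  expect_error(estimate_background(vol, small), "fewer than the minimum")
  empty <- fet_mask(array(0L, c(10, 10, 10)), reference = vol)
  expect_error(estimate_background(vol, empty), "empty")
})

test_that("background mean on a noisy phantom lands within the standard-error bound", {
  # generator draws background ~ N(1, 0.05); an ROI of ~10^4 voxels has
  # standard error ~ 0.0005, so 1 +/- 0.005 is a 10-sigma band
  spec <- phantom_spec(grid_shape = c(40, 40, 20), spacing = c(2, 2, 2),
                       background_mean = 1, background_sd = 0.05,
                       lesions = list(list(centre = c(10, 20, 10),
                                           semi_axes_mm = c(8, 8, 8),
                                           tbr = 2, sd = 0)),
                       seed = 21L)
  ph <- make_static_phantom(spec)
  big_roi <- fet_mask(array(ph$lesion_mask$values == 0 &
                              ph$background_mask$values == 0,
                            dim(ph$volume$values)),
                      reference = ph$volume)
  big_roi$values[1:20, , ] <- 0L   # keep away from the lesion half
  bg <- estimate_background(ph$volume, big_roi)
  expect_gt(bg$n_voxels, 1e4)
  expect_lt(abs(bg$mean_suv - 1), 0.005)
})

test_that("segmentation threshold is factor x background mean and matches the brute-force scan", {
  spec <- tiny_phantom(tbr = 2.5, seed = 3)
  ph <- make_static_phantom(spec)
  bg <- estimate_background(ph$volume, ph$background_mask)
  expect_equal(bg$mean_suv, 1)   # noiseless phantom
  seg <- segment_lesion(ph$volume, bg,
                        segmentation_config(min_component_ml = 0))
  expect_equal(seg$threshold_suv, 1.6)
  expect_identical(seg$mask$values,
                   oracle_threshold_mask(ph$volume$values, seg$threshold_suv))
  expect_identical(seg$mask$values, ph$lesion_mask$values)
})

test_that("a uniform sub-threshold volume segments to an empty mask without error", {
  vol <- volume_grid(array(1, c(8, 8, 4)), spacing = c(2, 2, 2))
  bg <- structure(list(mean_suv = 1, sd_suv = 0, n_voxels = 256),
                  class = "background_estimate")
  seg <- segment_lesion(vol, bg)
  expect_equal(sum(seg$mask$values), 0)
})

test_that("small components are filtered and a seed point selects its component", {
  vals <- array(1, c(16, 16, 8))
  vals[3:6, 3:6, 3:6] <- 3      # 64-voxel component (0.512 ml at 2mm voxels)
  vals[12, 12, 4] <- 3          # single-voxel speck (0.008 ml)
  vals[12:14, 3:5, 3:5] <- 3    # 27-voxel component (0.216 ml)
  vol <- volume_grid(vals, spacing = c(2, 2, 2))
  bg <- structure(list(mean_suv = 1, sd_suv = 0, n_voxels = 500),
                  class = "background_estimate")

  seg <- segment_lesion(vol, bg, segmentation_config(min_component_ml = 0.1))
  expect_equal(sum(seg$mask$values), 64 + 27)   # speck removed
  expect_equal(seg$n_components_removed, 1)

  seeded <- segment_lesion(vol, bg,
                           segmentation_config(min_component_ml = 0.1,
                                               seed_point = c(4, 4, 4)))
  expect_equal(sum(seeded$mask$values), 64)
  expect_true(all(seeded$mask$values[3:6, 3:6, 3:6] == 1))

  expect_error(segment_lesion(vol, bg,
                              segmentation_config(seed_point = c(99, 1, 1))),
               "outside")
})

test_that("uptake metrics follow the TBR definitions, including the closed 1.6 boundary", {
  vals <- array(1, c(6, 6, 2))
  vals[1:2, 1, 1] <- c(3.2, 2.4)
  vol <- volume_grid(vals, spacing = c(2, 2, 2))
  segv <- array(0L, c(6, 6, 2)); segv[1:2, 1, 1] <- 1L
  seg <- fet_mask(segv, reference = vol, label = "pet_segmentation")
  bg <- structure(list(mean_suv = 1.6, sd_suv = 0, n_voxels = 200),
                  class = "background_estimate")
  m <- compute_uptake_metrics(vol, seg, bg)
  expect_equal(m$tbr_max, 2.0)
  expect_equal(m$tbr_mean, 1.75)
  expect_true(m$tbr_mean <= m$tbr_max)
  expect_equal(m$pet_volume_ml, 2 * 0.008)
  expect_true(m$pet_positive)

  # TBR_max exactly at the 1.6 boundary counts as PET-positive
  vals2 <- array(1, c(6, 6, 2)); vals2[1, 1, 1] <- 1.6
  vol2 <- volume_grid(vals2, spacing = c(2, 2, 2))
  segv2 <- array(0L, c(6, 6, 2)); segv2[1, 1, 1] <- 1L
  bg1 <- structure(list(mean_suv = 1, sd_suv = 0, n_voxels = 200),
                   class = "background_estimate")
  m2 <- compute_uptake_metrics(vol2, fet_mask(segv2, reference = vol2), bg1)
  expect_equal(m2$tbr_max, 1.6)
  expect_true(m2$pet_positive)
})

test_that("an empty segmentation still yields a global-maximum TBR_max and volume 0", {
  vals <- array(1, c(8, 8, 4)); vals[4, 4, 2] <- 1.3
  vol <- volume_grid(vals, spacing = c(2, 2, 2))
  seg <- fet_mask(array(0L, c(8, 8, 4)), reference = vol)
  bg <- structure(list(mean_suv = 1, sd_suv = 0, n_voxels = 200),
                  class = "background_estimate")
  m <- compute_uptake_metrics(vol, seg, bg)
  expect_true(m$segmentation_empty)
  expect_equal(m$tbr_max, 1.3)
  expect_true(is.na(m$tbr_mean))
  expect_equal(m$pet_volume_ml, 0)
  expect_false(m$pet_positive)
})

test_that("TBR metrics are invariant under global rescaling of the volume", {
  spec <- tiny_phantom(tbr = 2.2, seed = 9, sd = 0.03)
  ph <- make_static_phantom(spec)
  bg <- estimate_background(ph$volume, ph$background_mask)
  seg <- segment_lesion(ph$volume, bg)
  m1 <- compute_uptake_metrics(ph$volume, seg$mask, bg)
  for (k in c(0.5, 3)) {
    vol_k <- volume_grid(ph$volume$values * k, spacing = ph$volume$spacing)
    bg_k <- estimate_background(vol_k, ph$background_mask)
    seg_k <- segment_lesion(vol_k, bg_k)
    m_k <- compute_uptake_metrics(vol_k, seg_k$mask, bg_k)
    expect_equal(m_k$tbr_max, m1$tbr_max, tolerance = 1e-12)
    expect_equal(m_k$tbr_mean, m1$tbr_mean, tolerance = 1e-12)
    expect_equal(m_k$pet_volume_ml, m1$pet_volume_ml)
  }
})

test_that("raising the threshold factor never increases the PET volume", {
  spec <- tiny_phantom(tbr = 2.5, seed = 31, sd = 0.3)
  ph <- make_static_phantom(spec)
  bg <- estimate_background(ph$volume, ph$background_mask)
  vols <- vapply(c(1.2, 1.4, 1.6, 1.8, 2.0), function(f) {
    seg <- segment_lesion(ph$volume, bg,
                          segmentation_config(threshold_factor = f,
                                              min_component_ml = 0))
    mask_volume_ml(seg$mask)
  }, numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("summation images are duration-weighted and reject unaligned windows", {
  sched <- frame_schedule(c(0, 5), c(5, 15))
  vals <- array(0, c(4, 4, 2, 2))
  vals[, , , 1] <- 1; vals[, , , 2] <- 4
  ser <- dynamic_series(vals, sched, spacing = c(2, 2, 2))
  s <- summation_image(ser, 0, 15)
  expect_equal(unique(as.vector(s$values)), (5 * 1 + 10 * 4) / 15)

  sched6 <- default_schedule()
  vals6 <- array(2, c(4, 4, 2, 6))
  ser6 <- dynamic_series(vals6, sched6, spacing = c(2, 2, 2))
  expect_error(summation_image(ser6, 22, 40), "frame boundaries")
  expect_error(summation_image(ser6, 20, 45), "outside")

  # full-schedule summation with uniform durations equals the plain mean
  schedU <- frame_schedule(seq(0, 25, 5), seq(5, 30, 5))
  set.seed(5)
  valsU <- array(runif(4 * 4 * 2 * 6), c(4, 4, 2, 6))
  serU <- dynamic_series(valsU, schedU, spacing = c(2, 2, 2))
  sU <- summation_image(serU, 0, 30)
  expect_equal(sU$values, apply(valsU, 1:3, mean), tolerance = 1e-12)
})

test_that("the mirrored background ROI reflects across the mid-sagittal plane", {
  vol <- volume_grid(array(1, c(21, 20, 10)), spacing = c(2, 2, 2))
  roi <- mirrored_background_roi(vol, centre = c(6, 10, 5),
                                 semi_axes_mm = c(6, 6, 6))
  idx <- which(roi$values > 0, arr.ind = TRUE)
  expect_equal(mean(idx[, 1]), 21 + 1 - 6, tolerance = 0.2)
  expect_gt(sum(roi$values), 50)
})
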