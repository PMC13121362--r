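make_curve <- function(values, mids = default_schedule()$mid_min) {
  fetquant:::new_tac(mids, values, "whole_roi", NA_integer_)
}

test_that("isocontour ROI equals the brute-force fraction-of-max scan", {
  spec <- tiny_phantom(tbr = 2.5, seed = 17, sd = 0.2)
  ph <- make_static_phantom(spec)
  roi <- isocontour_roi(ph$volume, 0.9)
  oracle <- oracle_threshold_mask(ph$volume$values, 0.9 * max(ph$volume$values))
  expect_identical(roi$values, oracle)
  expect_gt(sum(roi$values), 0)   # non-empty by construction

  # Gaussian-profile lesion: ROI still matches per-voxel comparison
  d <- c(16, 16, 8)
  g <- array(0, d)
  for (z in 1:8) for (y in 1:16) for (x in 1:16)
    g[x, y, z] <- 3 * exp(-((x - 8)^2 + (y - 8)^2 + (z - 4)^2) / 10) + 0.5
  vg <- volume_grid(g, spacing = c(2, 2, 2))
  roi_g <- isocontour_roi(vg, 0.9)
  expect_identical(roi_g$values, oracle_threshold_mask(g, 0.9 * max(g)))

  # constant image: everything qualifies
  cv <- volume_grid(array(2, c(4, 4, 2)), spacing = c(2, 2, 2))
  expect_equal(sum(isocontour_roi(cv, 0.9)$values), 32)
  # a search mask restricts both the maximum and the ROI
  sm <- fet_mask(array(rep(c(1L, 0L), c(8, 24)), c(4, 4, 2)), reference = cv)
  expect_equal(sum(isocontour_roi(cv, 0.9, sm)$values), 8)
})

test_that("TAC extraction reproduces generator curves and the weighted-mean slice identity", {
  ds <- dynamic_spec(curve_family = "increasing", noise_sd_rel = 0, seed = 2)
  dp <- make_dynamic_phantom(tiny_phantom(tbr = 2.5, seed = 2), ds)
  tac <- extract_tac(dp$series, dp$lesion_mask)
  nominal <- fetquant:::family_curve(ds) * 2.5
  expect_equal(tac$values, nominal, tolerance = 1e-12)
  expect_equal(tac$mid_min, ds$schedule$mid_min)

  # single-voxel ROI equals that voxel's frame values
  one <- array(0L, dim(dp$lesion_mask$values)); one[6, 10, 5] <- 1L
  roi1 <- fet_mask(one, reference = dp$lesion_mask)
  tac1 <- extract_tac(dp$series, roi1)
  expect_equal(tac1$values, dp$series$values[6, 10, 5, ])

  # slice TACs recombine to the whole-ROI curve by voxel-count weighting
  slices <- extract_slice_tacs(dp$series, dp$lesion_mask, min_slice_voxels = 1)
  counts <- vapply(slices, function(s)
    sum(dp$lesion_mask$values[, , s$slice_index]), numeric(1))
  recon <- Reduce(`+`, Map(function(s, w) s$values * w, slices, counts)) /
    sum(counts)
  expect_equal(recon, tac$values, tolerance = 1e-12)

  # slices below the voxel minimum are skipped and counted
  few <- dp$lesion_mask
  few$values[, , ] <- 0L
  few$values[6:8, 10, 5] <- 1L      # 3 voxels on slice 5
  few$values[6:7, 10, 6] <- 1L      # 2 voxels on slice 6
  sl <- extract_slice_tacs(dp$series, few, min_slice_voxels = 3)
  expect_equal(length(sl), 1)
  expect_equal(attr(sl, "n_skipped"), 1)

  expect_error(extract_tac(dp$series,
                           fet_mask(array(0L, dim(few$values)),
                                    reference = few)), "empty")
})

test_that("TAC classification follows the operational three-class rule", {
  cfg <- kinetic_config()
  # continuously rising curve
  expect_equal(classify_tac(make_curve(c(1, 1.8, 2.2, 2.4, 2.45, 2.5)), cfg)$curve_class,
               "increasing")
  # rise then plateau within the band
  expect_equal(classify_tac(make_curve(c(1, 2.3, 2.5, 2.45, 2.42, 2.4)), cfg)$curve_class,
               "increasing")
  # peak at 12.5 min then steady fall to 75% of peak: relative late change -0.25
  res <- classify_tac(make_curve(c(1.8, 2.3, 2.5, 2.3, 2.1, 1.875)), cfg)
  expect_equal(res$curve_class, "decreasing")
  expect_equal(res$evidence$rel_late_change, -0.25)
  expect_equal(res$evidence$ttp, 12.5)
  # flat curve with +/-5% jitter stays stable
  expect_equal(classify_tac(make_curve(2.5 * c(0.98, 1.02, 1, 0.97, 1.01, 0.99)), cfg)$curve_class,
               "stable")
  expect_error(classify_tac(make_curve(c(1, 2, 3), mids = c(2.5, 7.5, 12.5))),
               "at least 4 frames")
})

test_that("classification is invariant under positive rescaling of the curve", {
  set.seed(77)
  sched <- default_schedule()
  for (i in 1:50) {
    v <- pmax(runif(6, 0.5, 3), 0.01)
    base_cls <- classify_tac(make_curve(v))$curve_class
    for (k in c(0.01, 0.5, 7, 1000)) {
      expect_equal(classify_tac(make_curve(v * k))$curve_class, base_cls)
    }
  }
})

test_that("time to peak uses the earliest maximum and never exceeds the last mid-time", {
  expect_equal(time_to_peak(make_curve(c(1, 2, 3, 4, 5, 6))), 35)
  expect_equal(time_to_peak(make_curve(c(1, 5, 5, 2), mids = c(2.5, 7.5, 12.5, 17.5))),
               7.5)
  set.seed(12)
  for (i in 1:25) {
    v <- runif(6)
    expect_lte(time_to_peak(make_curve(v)), 35)
  }
  # generator round-trip: noiseless peak parameter is recovered exactly
  for (pt in c(7.5, 12.5, 17.5, 25)) {
    tc <- make_tacs(dynamic_spec(curve_family = "decreasing",
                                 peak_time_min = pt), 1)
    expect_equal(time_to_peak(tc$curves[[1]]), pt)
  }
})

test_that("TTP_min takes the shortest TTP repeated in adjacent slices, with flagged fallback", {
  mk_slice <- function(ttp, z) {
    mids <- default_schedule()$mid_min
    v <- rep(1, 6); v[which(mids == ttp)] <- 2
    fetquant:::new_tac(mids, v, "single_slice", z)
  }
  cfg <- kinetic_config()
  whole <- make_curve(c(1, 1.2, 1.4, 1.6, 1.8, 2))   # TTP 35

  res <- ttp_min(Map(mk_slice, c(35, 35, 25, 25, 12.5), 1:5), cfg, whole)
  expect_equal(res$ttp_min, 25)   # 12.5 occurs in only one slice
  expect_false(res$ttp_min_fallback)
  expect_equal(unname(res$ttp_per_slice), c(35, 35, 25, 25, 12.5))

  res_all <- ttp_min(Map(mk_slice, rep(35, 4), 1:4), cfg, whole)
  expect_equal(res_all$ttp_min, 35)

  res_fb <- ttp_min(Map(mk_slice, c(35, 25, 12.5), 1:3), cfg, whole)
  expect_true(res_fb$ttp_min_fallback)
  expect_equal(res_fb$ttp_min, 35)   # whole-ROI TTP
})

test_that("tumour-level class applies the two-adjacent-slice decreasing rule", {
  mids <- default_schedule()$mid_min
  inc <- c(1, 1.8, 2.2, 2.4, 2.45, 2.5)
  dec <- c(1.8, 2.3, 2.5, 2.3, 2.1, 1.8)
  sta <- 2.5 * c(0.99, 0.99, 1, 0.99, 0.99, 0.99)
  mk <- function(v, z) fetquant:::new_tac(mids, v, "single_slice", z)

  # whole-ROI increasing but two adjacent decreasing slices => decreasing
  r1 <- classify_tumour_kinetics(Map(mk, list(inc, dec, dec, inc), 1:4),
                                 make_curve(inc))
  expect_equal(r1$curve_class, "decreasing")
  expect_true(r1$heterogeneous_decreasing)

  # everything increasing stays increasing
  r2 <- classify_tumour_kinetics(Map(mk, list(inc, inc, inc), 1:3),
                                 make_curve(inc))
  expect_equal(r2$curve_class, "increasing")

  # non-adjacent decreasing slices do not overturn a stable whole-ROI class
  r3 <- classify_tumour_kinetics(Map(mk, list(dec, sta, dec, sta), 1:4),
                                 make_curve(sta))
  expect_equal(r3$curve_class, "stable")
})

test_that("kinetic classes and TTP are recovered from generated curves", {
  # noiseless: 100% recovery and exact TTP for every family
  for (fam in c("increasing", "stable", "decreasing")) {
    tc <- make_tacs(dynamic_spec(curve_family = fam, peak_time_min = 12.5), 5)
    cls <- vapply(tc$curves, function(cv) classify_tac(cv)$curve_class,
                  character(1))
    expect_true(all(cls == fam))
    ttps <- vapply(tc$curves, time_to_peak, numeric(1))
    expect_true(all(ttps == tc$true_ttp))
  }
  # 2% relative noise: at least 95% of 100 curves per family (seeded)
  for (fam in c("increasing", "stable", "decreasing")) {
    tc <- make_tacs(dynamic_spec(curve_family = fam, peak_time_min = 12.5,
                                 noise_sd_rel = 0.02, seed = 1), 100)
    cls <- vapply(tc$curves, function(cv) classify_tac(cv)$curve_class,
                  character(1))
    expect_gte(mean(cls == fam), 0.95)
  }
})
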