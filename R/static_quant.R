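# Static uptake quantification: contralateral background estimation,
# 1.6 x background threshold segmentation, TBR metrics, PET-RANO positivity,
# and summation images from dynamic series.

#' Segmentation configuration
#'
#' @param threshold_factor multiplier on the mean background SUV defining the
#'   lower segmentation threshold; 1.6 by convention for amino-acid PET.
#' @param connectivity neighbourhood for component labelling (6, 18 or 26).
#' @param min_component_ml smallest connected component retained, in ml;
#'   suppresses single-voxel noise. Set to 0 to keep everything.
#' @param seed_point optional 1-based voxel index `c(x, y, z)`; when given,
#'   only the supra-threshold component containing (or nearest to) the seed
#'   is kept — a reproducible stand-in for the operator's semiautomatic
#'   lesion selection.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(threshold_factor = 1.6, connectivity = 26L,
                                min_component_ml = 0.1, seed_point = NULL) {
  if (threshold_factor <= 1) stop("'threshold_factor' must be > 1")
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  if (min_component_ml < 0) stop("'min_component_ml' must be >= 0")
  if (!is.null(seed_point) && length(seed_point) != 3L)
    stop("'seed_point' must be a voxel index c(x, y, z)")
  structure(list(threshold_factor = threshold_factor,
                 connectivity = as.integer(connectivity),
                 min_component_ml = min_component_ml,
                 seed_point = seed_point),
            class = "segmentation_config")
}

#' Estimate background activity in a reference ROI
#'
#' Mean and SD of SUV within a background region of interest, canonically a
#' crescent/ellipsoid in the healthy contralateral hemisphere. The mean
#' anchors both the segmentation threshold and all TBR values.
#'
#' @param volume a [volume_grid()].
#' @param roi a [fet_mask()] on the same grid.
#' @param min_voxels smallest acceptable ROI (default 100 voxels); tiny ROIs
#'   give unstable background means.
#' @return A `background_estimate` with `mean_suv`, `sd_suv`, `n_voxels`.
#' @export
estimate_background <- function(volume, roi, min_voxels = 100L) {
  stopifnot_same_grid(volume, roi)
  n <- sum(roi$values)
  if (n == 0) stop("background ROI is empty")
  if (n < min_voxels)
    stop(sprintf("background ROI has %d voxels, fewer than the minimum %d", n, min_voxels))
  v <- volume$values[roi$values > 0]
  m <- mean(v)
  if (m <= 0) stop("non-positive background mean; check ROI placement")
  structure(list(mean_suv = m, sd_suv = stats::sd(v), n_voxels = n),
            class = "background_estimate")
}

#' @export
print.background_estimate <- function(x, ...) {
  cat(sprintf("<background_estimate> mean SUV %.4g (sd %.3g) over %d voxels\n",
              x$mean_suv, x$sd_suv, x$n_voxels))
  invisible(x)
}

#' Build a mirrored contralateral background ROI
#'
#' Reflects a user-given centre across the mid-sagittal (x) plane of the grid
#' and draws an ellipsoid there — a geometric helper for placing a healthy
#' contralateral background region without any anatomical model.
#'
#' @param volume a [volume_grid()].
#' @param centre 1-based voxel index `c(x, y, z)` of the lesion (or ROI seed)
#'   to mirror.
#' @param semi_axes_mm ellipsoid semi-axes in mm.
#' @return A [fet_mask()] with label `"background_roi"`.
#' @export
mirrored_background_roi <- function(volume, centre, semi_axes_mm = c(10, 10, 10)) {
  d <- dim(volume$values)
  mirrored <- c(d[1] + 1 - centre[1], centre[2], centre[3])
  fet_mask(ellipsoid_mask_values(d, volume$spacing, mirrored, semi_axes_mm),
           reference = volume, label = "background_roi")
}

# binary ellipsoid on a voxel grid (1-based centre, semi-axes in mm)
ellipsoid_mask_values <- function(dim3, spacing, centre, semi_axes_mm) {
  x <- (seq_len(dim3[1]) - centre[1]) * spacing[1] / semi_axes_mm[1]
  y <- (seq_len(dim3[2]) - centre[2]) * spacing[2] / semi_axes_mm[2]
  z <- (seq_len(dim3[3]) - centre[3]) * spacing[3] / semi_axes_mm[3]
  r2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  array(as.integer(r2 <= 1), dim3)
}

#' Threshold segmentation of the PET lesion
#'
#' Voxels with SUV at or above `threshold_factor x background mean` form the
#' PET volume. Connected components smaller than `min_component_ml` are
#' discarded; with a `seed_point`, only the component containing (or, if the
#' seed itself is sub-threshold, nearest to) the seed is kept. An empty mask
#' is a valid result (PET-negative tumour), not an error.
#'
#' @param volume a [volume_grid()].
#' @param background a `background_estimate` from [estimate_background()].
#' @param config a [segmentation_config()].
#' @return A list with `mask` ([fet_mask()], label `"pet_segmentation"`),
#'   `threshold_suv`, and `n_components_removed`.
#' @export
segment_lesion <- function(volume, background,
                           config = segmentation_config()) {
  if (background$mean_suv <= 0) stop("background mean must be positive")
  thr <- config$threshold_factor * background$mean_suv
  fg <- volume$values >= thr
  d <- dim(volume$values)
  n_removed <- 0L

  if (any(fg) && (config$min_component_ml > 0 || !is.null(config$seed_point))) {
    lab <- label_components(fg, config$connectivity)
    sizes <- tabulate(lab[lab > 0L])
    vox_ml <- voxel_volume_ml(volume)
    keep <- sizes * vox_ml >= config$min_component_ml
    if (!is.null(config$seed_point)) {
      sp <- as.integer(config$seed_point)
      if (any(sp < 1L) || any(sp > d))
        stop("seed_point lies outside the volume")
      cand <- which(keep)
      if (length(cand) > 0) {
        seed_lab <- lab[sp[1], sp[2], sp[3]]
        sel <- if (seed_lab > 0L && keep[seed_lab]) {
          seed_lab
        } else {
          # nearest retained component to the seed (mm distance)
          idx <- which(lab > 0L & array(keep[pmax(lab, 1L)], d), arr.ind = TRUE)
          labs_at <- lab[lab > 0L & array(keep[pmax(lab, 1L)], d)]
          dmm <- sweep(idx, 2, sp) %*% diag(volume$spacing)
          labs_at[which.min(rowSums(dmm^2))]
        }
        keep2 <- logical(length(sizes)); keep2[sel] <- TRUE
        keep <- keep & keep2
      }
    }
    n_removed <- sum(sizes > 0) - sum(keep)
    fg <- array(lab > 0L & keep[pmax(lab, 1L)], d)
  }

  list(mask = fet_mask(fg, reference = volume, label = "pet_segmentation"),
       threshold_suv = thr,
       n_components_removed = n_removed)
}

#' Uptake metrics and PET-RANO positivity
#'
#' SUV_max/SUV_mean within the segmented PET volume, TBR_max/TBR_mean as
#' their ratios to the background mean, segmented volume in ml, and PET
#' positivity (TBR_max >= 1.6, boundary included). For an empty segmentation
#' (PET-negative tumour) the TBR_max is still reported from the global
#' maximum within `search_mask` (or the whole volume), so that negative cases
#' yield a measurable TBR_max >= 1 rather than a missing value; segment-based
#' metrics are NA and the PET volume is 0.
#'
#' @param volume a [volume_grid()].
#' @param segmentation a [fet_mask()] from [segment_lesion()].
#' @param background a `background_estimate`.
#' @param search_mask optional [fet_mask()] restricting the search region used
#'   for the empty-segmentation TBR_max.
#' @param positivity_threshold TBR_max cut-point for PET positivity (1.6).
#' @return An `uptake_metrics` list: `suv_max`, `suv_mean`, `tbr_max`,
#'   `tbr_mean`, `pet_volume_ml`, `pet_positive`, `segmentation_empty`.
#' @export
compute_uptake_metrics <- function(volume, segmentation, background,
                                   search_mask = NULL,
                                   positivity_threshold = 1.6) {
  stopifnot_same_grid(volume, segmentation)
  if (background$mean_suv <= 0) stop("background mean must be positive")
  bg <- background$mean_suv
  n_seg <- sum(segmentation$values)
  if (n_seg > 0) {
    v <- volume$values[segmentation$values > 0]
    suv_max <- max(v); suv_mean <- mean(v)
    out <- list(suv_max = suv_max, suv_mean = suv_mean,
                tbr_max = suv_max / bg, tbr_mean = suv_mean / bg,
                pet_volume_ml = n_seg * voxel_volume_ml(volume),
                segmentation_empty = FALSE)
  } else {
    region <- if (is.null(search_mask)) volume$values else {
      stopifnot_same_grid(volume, search_mask)
      volume$values[search_mask$values > 0]
    }
    suv_max <- max(region)
    out <- list(suv_max = suv_max, suv_mean = NA_real_,
                tbr_max = suv_max / bg, tbr_mean = NA_real_,
                pet_volume_ml = 0, segmentation_empty = TRUE)
  }
  out$pet_positive <- out$tbr_max >= positivity_threshold
  structure(out, class = "uptake_metrics")
}

#' @export
print.uptake_metrics <- function(x, ...) {
  cat(sprintf("<uptake_metrics> TBR_max %.3f, TBR_mean %s, PET volume %.3g ml, %s\n",
              x$tbr_max,
              if (is.na(x$tbr_mean)) "NA" else sprintf("%.3f", x$tbr_mean),
              x$pet_volume_ml,
              if (x$pet_positive) "PET-positive" else "PET-negative"))
  invisible(x)
}

#' Duration-weighted summation image over a time window
#'
#' Mean SUV image over the frames whose intervals tile `[window_start_min,
#' window_end_min]`, weighted by frame duration — e.g. the standard 20-40 min
#' image for static analysis, or 10-30 min for the kinetic isocontour ROI.
#' The window must coincide with frame boundaries; anything else is an error
#' rather than a silent partial-frame interpolation.
#'
#' @param series a [dynamic_series()].
#' @param window_start_min,window_end_min window in minutes post-injection.
#' @return A [volume_grid()].
#' @export
summation_image <- function(series, window_start_min, window_end_min) {
  s <- series$schedule
  if (window_end_min <= window_start_min) stop("empty summation window")
  if (window_start_min < s$start_min[1] || window_end_min > s$end_min[length(s)])
    stop("summation window lies outside the acquisition schedule")
  sel <- which(s$start_min >= window_start_min & s$end_min <= window_end_min)
  if (length(sel) == 0 ||
      !isTRUE(all.equal(min(s$start_min[sel]), window_start_min)) ||
      !isTRUE(all.equal(max(s$end_min[sel]), window_end_min)) ||
      !isTRUE(all.equal(sum(s$duration_min[sel]),
                        window_end_min - window_start_min)))
    stop("summation window must coincide with frame boundaries")
  w <- s$duration_min[sel] / sum(s$duration_min[sel])
  d <- dim(series$values)
  acc <- array(0, d[1:3])
  for (k in seq_along(sel))
    acc <- acc + w[k] * series$values[, , , sel[k], drop = TRUE]
  volume_grid(acc, spacing = series$spacing, affine = series$affine)
}
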