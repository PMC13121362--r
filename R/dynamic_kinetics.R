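# Dynamic PET kinetics: 90% isocontour ROI on the 10-30 min summation image,
# time-activity-curve (TAC) extraction (whole-ROI and per axial slice),
# three-class kinetic pattern classification, TTP and TTP_min.

#' Kinetic analysis configuration
#'
#' Operational parameters for TAC classification and TTP_min. The qualitative
#' pattern definitions (continuous increase or rise-then-plateau; initial
#' peak with constant decline; fluctuation within +/-10% of the peak) are
#' made deterministic via these quantities.
#'
#' @param isocontour_fraction fraction of the maximum SUV defining the
#'   kinetic ROI on the 10-30 min summation image (default 0.90).
#' @param stability_band relative half-width around the peak within which the
#'   curve counts as stable/plateau (default 0.10, i.e. +/-10% of peak).
#' @param early_window_end_min end of the early uptake window used for the
#'   relative rise (default 5 min).
#' @param decline_threshold relative post-peak drop that defines a decreasing
#'   curve (default 0.10).
#' @param min_consecutive_slices adjacent slices required for TTP_min and for
#'   heterogeneous decreasing patterns (default 2).
#' @param min_slice_voxels smallest ROI cross-section (voxels) for which a
#'   single-slice TAC is analysed (default 3).
#' @return A `kinetic_config` list.
#' @export
kinetic_config <- function(isocontour_fraction = 0.90, stability_band = 0.10,
                           early_window_end_min = 5, decline_threshold = 0.10,
                           min_consecutive_slices = 2L, min_slice_voxels = 3L) {
  stopifnot(isocontour_fraction > 0, isocontour_fraction < 1,
            stability_band > 0, stability_band < 1,
            decline_threshold > 0, min_consecutive_slices >= 2,
            min_slice_voxels >= 1)
  structure(list(isocontour_fraction = isocontour_fraction,
                 stability_band = stability_band,
                 early_window_end_min = early_window_end_min,
                 decline_threshold = decline_threshold,
                 min_consecutive_slices = as.integer(min_consecutive_slices),
                 min_slice_voxels = as.integer(min_slice_voxels)),
            class = "kinetic_config")
}

#' Isocontour ROI on a summation image
#'
#' Voxels with SUV at or above `fraction` times the maximum SUV (within
#' `search_mask` when given, else globally). Non-empty by construction: the
#' maximum voxel always qualifies.
#'
#' @param summation a [volume_grid()], canonically the 10-30 min summation.
#' @param fraction isocontour fraction in (0,1); 0.90 by convention.
#' @param search_mask optional [fet_mask()] restricting both the maximum
#'   search and the ROI.
#' @return A [fet_mask()] with label `"isocontour_roi"`.
#' @export
isocontour_roi <- function(summation, fraction = 0.90, search_mask = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  v <- summation$values
  if (!is.null(search_mask)) {
    stopifnot_same_grid(summation, search_mask)
    inside <- search_mask$values > 0
    if (!any(inside)) stop("empty search mask")
    mx <- max(v[inside])
  } else {
    inside <- TRUE
    mx <- max(v)
  }
  if (mx <= 0) stop("degenerate (all-zero) summation image")
  fet_mask(array(v >= fraction * mx & inside, dim(v)),
           reference = summation, label = "isocontour_roi")
}

#' Extract a whole-ROI time-activity curve
#'
#' Mean SUV within the ROI for each dynamic frame, against frame mid-times.
#'
#' @param series a [dynamic_series()].
#' @param roi non-empty [fet_mask()] on the series grid.
#' @return A `tac` object: `mid_min`, `values`, `roi_scope`, `slice_index`.
#' @export
extract_tac <- function(series, roi) {
  stopifnot_same_grid(series, roi)
  sel <- roi$values > 0
  if (!any(sel)) stop("empty ROI")
  nf <- dim(series$values)[4]
  vals <- vapply(seq_len(nf), function(k)
    mean(series$values[, , , k, drop = TRUE][sel]), numeric(1))
  new_tac(series$schedule$mid_min, vals, "whole_roi", NA_integer_)
}

new_tac <- function(mid_min, values, roi_scope, slice_index) {
  stopifnot(length(mid_min) == length(values), !is.unsorted(mid_min, strictly = TRUE))
  structure(list(mid_min = mid_min, values = values,
                 roi_scope = roi_scope, slice_index = slice_index),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  scope <- if (x$roi_scope == "whole_roi") "whole ROI" else
    sprintf("slice %d", x$slice_index)
  cat(sprintf("<tac> %s, %d frames; SUV %s\n", scope, length(x$values),
              paste(sprintf("%.3g", x$values), collapse = ", ")))
  invisible(x)
}

#' Extract per-slice time-activity curves
#'
#' One TAC per axial (z) slice intersecting the ROI, in slice order. Slices
#' whose ROI cross-section is below `min_slice_voxels` are skipped (their
#' count is attached as attribute `n_skipped`): single-voxel TACs are noise
#' dominated.
#'
#' @param series a [dynamic_series()].
#' @param roi non-empty [fet_mask()].
#' @param min_slice_voxels minimum ROI voxels per slice (default 3).
#' @return List of `tac` objects with attribute `n_skipped`.
#' @export
extract_slice_tacs <- function(series, roi, min_slice_voxels = 3L) {
  stopifnot_same_grid(series, roi)
  if (sum(roi$values) == 0) stop("empty ROI")
  counts <- apply(roi$values, 3, sum)
  slices <- which(counts > 0)
  use <- slices[counts[slices] >= min_slice_voxels]
  n_skipped <- length(slices) - length(use)
  nf <- dim(series$values)[4]
  out <- lapply(use, function(z) {
    sel <- roi$values[, , z] > 0
    vals <- vapply(seq_len(nf), function(k)
      mean(series$values[, , z, k][sel]), numeric(1))
    new_tac(series$schedule$mid_min, vals, "single_slice", as.integer(z))
  })
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Time to peak of a TAC
#'
#' Mid-time of the earliest frame attaining the curve maximum (ties broken to
#' the earliest frame, matching the "initial peak" reading).
#'
#' @param curve a `tac`.
#' @return TTP in minutes.
#' @export
time_to_peak <- function(curve) {
  if (length(curve$values) == 0) stop("empty curve")
  curve$mid_min[which.max(curve$values)]
}

#' Classify a time-activity curve
#'
#' Deterministic three-class rule. With peak index `p` (earliest global
#' maximum, value `s_p`), early uptake `s_early` (mean of frames with
#' mid-time <= `early_window_end_min`), relative rise
#' `R = (s_p - s_early)/s_p` and relative late change
#' `D = (s_last - s_p)/s_p`:
#' \itemize{
#'   \item increasing — a genuine rise (`R > stability_band`) whose level is
#'     maintained to the end (`D >= -stability_band`); this covers both a
#'     continuous increase (peak at the final frame, where `D = 0`) and a
#'     rise followed by a plateau. A curve that merely fluctuates within the
#'     stability band never counts as increasing, even when its noisy
#'     maximum happens to fall on the last frame;
#'   \item decreasing — `D < -decline_threshold` with post-peak values
#'     non-increasing within `stability_band * s_p` per step (initial peak,
#'     constant decline);
#'   \item stable — all values within `+/- stability_band * s_p` of the peak
#'     and neither rule above fired;
#'   \item otherwise the sign of the least-squares slope over the late window
#'     (mid-times beyond `early_window_end_min`) decides increasing /
#'     decreasing (stable on an exactly zero slope).
#' }
#'
#' @param curve a `tac` with at least 4 frames.
#' @param config a [kinetic_config()].
#' @return List with `curve_class` and `evidence` (peak index, TTP, relative
#'   rise, relative late change, rule fired).
#' @export
classify_tac <- function(curve, config = kinetic_config()) {
  s <- curve$values
  t <- curve$mid_min
  if (length(s) < 4) stop("TAC classification requires at least 4 frames")
  p <- which.max(s)
  s_p <- s[p]
  if (s_p <= 0) stop("degenerate TAC (non-positive peak)")
  early <- t <= config$early_window_end_min
  s_early <- if (any(early)) mean(s[early]) else s[1]
  rel_rise <- (s_p - s_early) / s_p
  rel_late <- (s[length(s)] - s_p) / s_p

  post <- s[p:length(s)]
  post_nonincreasing <- length(post) <= 1 ||
    all(diff(post) <= config$stability_band * s_p)

  cls <- NULL; rule <- NULL
  if (rel_rise > config$stability_band && rel_late >= -config$stability_band) {
    cls <- "increasing"
    rule <- if (p == length(s)) "continuous_rise" else "rise_then_plateau"
  } else if (rel_late < -config$decline_threshold && post_nonincreasing) {
    cls <- "decreasing"; rule <- "peak_then_decline"
  } else if (all(abs(s - s_p) <= config$stability_band * s_p)) {
    cls <- "stable"; rule <- "within_band"
  } else {
    late <- t > config$early_window_end_min
    if (sum(late) < 2) late <- rep(TRUE, length(t))
    slope <- stats::coef(stats::lm(s[late] ~ t[late]))[2]
    cls <- if (slope > 0) "increasing" else if (slope < 0) "decreasing" else "stable"
    rule <- "late_slope_fallback"
  }
  list(curve_class = cls,
       evidence = list(peak_index = p, ttp = t[p],
                       rel_rise = rel_rise, rel_late_change = rel_late,
                       rule = rule))
}

#' Minimal time to peak across tumour slices
#'
#' Per-slice TTPs are computed and the smallest TTP value occurring in at
#' least `min_consecutive_slices` adjacent slices is TTP_min. If no TTP value
#' repeats across adjacent slices, TTP_min falls back to the whole-ROI
#' curve's TTP and the result is flagged.
#'
#' @param slice_curves list of `tac` objects in slice order (from
#'   [extract_slice_tacs()]).
#' @param config a [kinetic_config()].
#' @param whole_roi_curve whole-ROI `tac`, required for the fallback.
#' @return List with `ttp_per_slice` (named by slice index), `ttp_min`, and
#'   `ttp_min_fallback` flag.
#' @export
ttp_min <- function(slice_curves, config = kinetic_config(),
                    whole_roi_curve = NULL) {
  if (length(slice_curves) == 0) stop("no slice curves")
  ttps <- vapply(slice_curves, time_to_peak, numeric(1))
  names(ttps) <- vapply(slice_curves, function(x)
    as.character(x$slice_index), character(1))
  k <- config$min_consecutive_slices
  runs <- rle(ttps)
  cand <- runs$values[runs$lengths >= k]
  if (length(cand) > 0) {
    list(ttp_per_slice = ttps, ttp_min = min(cand), ttp_min_fallback = FALSE)
  } else {
    if (is.null(whole_roi_curve))
      stop("no TTP value repeats across adjacent slices and no whole-ROI curve was supplied for the fallback")
    list(ttp_per_slice = ttps, ttp_min = time_to_peak(whole_roi_curve),
         ttp_min_fallback = TRUE)
  }
}

#' Tumour-level kinetic classification
#'
#' The tumour is decreasing when the whole-ROI curve classifies decreasing
#' (homogeneous pattern) or when at least `min_consecutive_slices` adjacent
#' slices each classify decreasing (heterogeneous pattern); otherwise the
#' whole-ROI class stands. TTP_min is computed per [ttp_min()].
#'
#' @param slice_curves list of `tac` objects in slice order.
#' @param whole_roi_curve whole-ROI `tac`.
#' @param config a [kinetic_config()].
#' @return A `kinetic_result`: `curve_class`, `per_slice_classes`,
#'   `ttp_per_slice`, `ttp_min`, `ttp_min_fallback`, `evidence`.
#' @export
classify_tumour_kinetics <- function(slice_curves, whole_roi_curve,
                                     config = kinetic_config()) {
  whole <- classify_tac(whole_roi_curve, config)
  per_slice <- vapply(slice_curves, function(cv)
    classify_tac(cv, config)$curve_class, character(1))
  runs <- rle(per_slice)
  hetero_dec <- any(runs$values == "decreasing" &
                    runs$lengths >= config$min_consecutive_slices)
  cls <- if (whole$curve_class == "decreasing" || hetero_dec)
    "decreasing" else whole$curve_class
  tt <- ttp_min(slice_curves, config, whole_roi_curve)
  structure(list(curve_class = cls,
                 whole_roi_class = whole$curve_class,
                 per_slice_classes = per_slice,
                 heterogeneous_decreasing = hetero_dec,
                 ttp_per_slice = tt$ttp_per_slice,
                 ttp_min = tt$ttp_min,
                 ttp_min_fallback = tt$ttp_min_fallback,
                 evidence = whole$evidence),
            class = "kinetic_result")
}

#' @export
print.kinetic_result <- function(x, ...) {
  cat(sprintf("<kinetic_result> class %s (whole-ROI %s), TTP_min %g min%s\n",
              x$curve_class, x$whole_roi_class, x$ttp_min,
              if (x$ttp_min_fallback) " [whole-ROI fallback]" else ""))
  invisible(x)
}
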