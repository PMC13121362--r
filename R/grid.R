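#' Construct a volumetric SUV grid
#'
#' A `volume_grid` holds a 3-D scalar field of standardized uptake values
#' (SUV, unitless) together with its voxel spacing in mm and a 4x4
#' voxel-to-world affine (NIfTI convention, 0-based voxel indices). The third
#' array axis is the axial (z) slice axis used by all slice-wise kinetics.
#'
#' @param values 3-D numeric array of SUV; negatives are clamped to zero with
#'   a warning (reconstruction noise commonly yields small negatives).
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param affine 4x4 voxel-to-world transform; defaults to `diag(spacing)`
#'   with a zero origin.
#' @return A `volume_grid` object.
#' @export
volume_grid <- function(values, spacing = c(1, 1, 1), affine = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3-D array")
  if (anyNA(values) || any(!is.finite(values)))
    stop("volume contains non-finite voxels")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 positive voxel edge lengths in mm")
  n_clamped <- sum(values < 0)
  if (n_clamped > 0) {
    warning(sprintf("%d negative SUV voxel(s) clamped to 0", n_clamped))
    values[values < 0] <- 0
  }
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L))) stop("'affine' must be 4x4")
  }
  structure(
    list(values = values, spacing = spacing, affine = affine,
         n_clamped = n_clamped),
    class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid> %dx%dx%d voxels, spacing %s mm, voxel %.4g ml\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = "x"),
              voxel_volume_ml(x)))
  cat(sprintf("  SUV range [%.3g, %.3g]", min(x$values), max(x$values)))
  if (x$n_clamped > 0) cat(sprintf("  (%d voxels clamped)", x$n_clamped))
  cat("\n")
  invisible(x)
}

#' Voxel volume in millilitres
#'
#' @param x a `volume_grid`, `fet_mask` or `dynamic_series`.
#' @return `prod(spacing)/1000` in ml.
#' @export
voxel_volume_ml <- function(x) prod(x$spacing) / 1000

#' Construct a binary mask aligned to a reference grid
#'
#' Masks are strictly binary and carry the geometry of their reference grid.
#' A geometry mismatch between a mask and the volume it is used with is a hard
#' error everywhere in the pipeline (silent resampling would corrupt Dice and
#' TBR values).
#'
#' @param values 3-D array coercible to {0,1} (logical or numeric).
#' @param reference optional `volume_grid` (or another mask) supplying
#'   spacing/affine; checked for shape agreement.
#' @param spacing,affine geometry, used when `reference` is NULL.
#' @param label role tag: one of `"pet_segmentation"`, `"flair"`, `"ce"`,
#'   `"background_roi"`, `"isocontour_roi"`, or `"generic"`.
#' @return A `fet_mask` object.
#' @export
fet_mask <- function(values, reference = NULL, spacing = c(1, 1, 1),
                     affine = NULL, label = "generic") {
  if (is.logical(values)) values <- array(as.integer(values), dim(values))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("mask 'values' must be a 3-D array")
  if (anyNA(values) || !all(values %in% c(0, 1)))
    stop("mask values must be strictly binary {0,1}")
  values <- array(as.integer(values), dim(values))
  if (!is.null(reference)) {
    if (!all(dim(values) == dim(reference$values)))
      stop("mask shape does not match reference grid")
    spacing <- reference$spacing
    affine <- reference$affine
  } else if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  label <- match.arg(label, c("pet_segmentation", "flair", "ce",
                              "background_roi", "isocontour_roi", "generic"))
  structure(
    list(values = values, spacing = as.numeric(spacing),
         affine = as.matrix(affine), label = label),
    class = "fet_mask")
}

#' @export
print.fet_mask <- function(x, ...) {
  cat(sprintf("<fet_mask> [%s] %s voxels on %s grid, %.4g ml\n", x$label,
              sum(x$values), paste(dim(x$values), collapse = "x"),
              mask_volume_ml(x)))
  invisible(x)
}

#' Mask volume in millilitres
#' @param mask a `fet_mask`.
#' @export
mask_volume_ml <- function(mask) sum(mask$values) * voxel_volume_ml(mask)

#' Check that two objects share a voxel grid
#'
#' Same array shape and affine (within `tol`). Used as a precondition by every
#' operation that combines a mask with a volume or another mask.
#'
#' @param a,b objects with `values` and `affine` fields.
#' @param tol absolute tolerance on affine entries.
#' @return TRUE invisibly, or an error.
#' @export
stopifnot_same_grid <- function(a, b, tol = 1e-6) {
  da <- dim(a$values)[1:3]; db <- dim(b$values)[1:3]
  if (!all(da == db))
    stop("grid mismatch: array shapes differ (", paste(da, collapse = "x"),
         " vs ", paste(db, collapse = "x"), ")")
  if (max(abs(a$affine - b$affine)) > tol)
    stop("grid mismatch: affines differ; inputs must be co-registered on a common grid")
  invisible(TRUE)
}

#' Construct a dynamic frame schedule
#'
#' Ordered, non-overlapping acquisition frames in minutes post-injection.
#' Frame mid-times (start+end)/2 are the time axis of all time-activity
#' curves and of TTP values.
#'
#' @param starts,ends numeric vectors of frame start/end times in minutes.
#' @return A `frame_schedule` object with `start_min`, `end_min`, `mid_min`.
#' @export
frame_schedule <- function(starts, ends) {
  starts <- as.numeric(starts); ends <- as.numeric(ends)
  if (length(starts) != length(ends) || length(starts) == 0)
    stop("'starts' and 'ends' must be non-empty and of equal length")
  if (any(ends <= starts)) stop("every frame must have end > start")
  if (starts[1] < 0) stop("first frame start must be >= 0")
  if (length(starts) > 1 && any(starts[-1] < ends[-length(ends)]))
    stop("frames must be non-overlapping and strictly increasing")
  structure(
    list(start_min = starts, end_min = ends,
         mid_min = (starts + ends) / 2,
         duration_min = ends - starts),
    class = "frame_schedule")
}

#' Default 0-40 min frame schedule
#'
#' Six frames (0-5, 5-10, 10-15, 15-20, 20-30, 30-40 min) whose mid-times
#' {2.5, 7.5, 12.5, 17.5, 25, 35} are the achievable TTP levels of the
#' kinetic analysis.
#'
#' @return A `frame_schedule`.
#' @export
default_schedule <- function() {
  frame_schedule(c(0, 5, 10, 15, 20, 30), c(5, 10, 15, 20, 30, 40))
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %g-%g min; mid-times: %s\n",
              length(x$mid_min), x$start_min[1], x$end_min[length(x$end_min)],
              paste(x$mid_min, collapse = ", ")))
  invisible(x)
}

#' @export
length.frame_schedule <- function(x) length(x$mid_min)

#' Construct a dynamic (4-D) SUV series
#'
#' @param values 4-D array (x, y, z, frame) of SUV.
#' @param schedule `frame_schedule` whose length equals the 4th dimension.
#' @param spacing,affine grid geometry shared by all frames.
#' @return A `dynamic_series` object.
#' @export
dynamic_series <- function(values, schedule, spacing = c(1, 1, 1),
                           affine = NULL) {
  if (!is.array(values) || length(dim(values)) != 4L)
    stop("'values' must be a 4-D array (x, y, z, frame)")
  if (!inherits(schedule, "frame_schedule"))
    stop("'schedule' must be a frame_schedule")
  if (dim(values)[4] != length(schedule))
    stop(sprintf("frame-count mismatch: series has %d frames, schedule %d",
                 dim(values)[4], length(schedule)))
  if (anyNA(values) || any(!is.finite(values)))
    stop("dynamic series contains non-finite voxels")
  n_clamped <- sum(values < 0)
  if (n_clamped > 0) {
    warning(sprintf("%d negative SUV voxel(s) clamped to 0", n_clamped))
    values[values < 0] <- 0
  }
  spacing <- as.numeric(spacing)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(
    list(values = values, schedule = schedule, spacing = spacing,
         affine = as.matrix(affine), n_clamped = n_clamped),
    class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dynamic_series> %dx%dx%d voxels x %d frames (%g-%g min)\n",
              d[1], d[2], d[3], d[4], x$schedule$start_min[1],
              x$schedule$end_min[length(x$schedule)]))
  invisible(x)
}

#' Extract one frame of a dynamic series as a volume_grid
#' @param series a `dynamic_series`.
#' @param frame frame index (1-based).
#' @export
series_frame <- function(series, frame) {
  stopifnot(frame >= 1, frame <= dim(series$values)[4])
  volume_grid(series$values[, , , frame, drop = TRUE],
              spacing = series$spacing, affine = series$affine)
}
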