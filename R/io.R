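# NIfTI reading/writing via RNifti; schedules as JSON/YAML.

nifti_affine <- function(img) {
  x <- RNifti::xform(img)
  m <- matrix(as.numeric(x), 4, 4)
  m[4, ] <- c(0, 0, 0, 1)
  m
}

as_nifti_image <- function(values, spacing, affine) {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- spacing
  RNifti::`sform<-`(img, structure(affine, code = 2L))
}

#' Read a static SUV volume from NIfTI
#'
#' Reads a 3-D NIfTI-1/2 file, taking spacing and affine from the header.
#' Negative SUV voxels are clamped to zero; the clamp count is available as
#' `$n_clamped` and reported with a warning.
#'
#' @param path path to a `.nii`/`.nii.gz` file with 3 spatial dimensions.
#' @return A [volume_grid()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L)
    stop("input is 4-D; use read_dynamic() with a frame schedule")
  if (length(d) != 3L) stop("expected a 3-D volume, got ", length(d), " dimensions")
  volume_grid(array(as.numeric(img), d),
              spacing = RNifti::pixdim(img)[1:3],
              affine = nifti_affine(img))
}

#' Write a static SUV volume to NIfTI
#' @param volume a [volume_grid()].
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  RNifti::writeNifti(as_nifti_image(volume$values, volume$spacing,
                                    volume$affine), path)
  invisible(path)
}

#' Read a dynamic 4-D SUV series from NIfTI
#'
#' @param path path to a 4-D NIfTI whose 4th dimension equals the number of
#'   schedule frames.
#' @param schedule a [frame_schedule()] describing the acquisition frames.
#' @return A [dynamic_series()].
#' @export
read_dynamic <- function(path, schedule) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!inherits(schedule, "frame_schedule"))
    stop("'schedule' must be a frame_schedule")
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4-D series, got ", length(d), " dimensions")
  if (d[4] != length(schedule))
    stop(sprintf("frame-count mismatch: file has %d frames, schedule %d",
                 d[4], length(schedule)))
  dynamic_series(array(as.numeric(img), d), schedule,
                 spacing = RNifti::pixdim(img)[1:3],
                 affine = nifti_affine(img))
}

#' Write a dynamic series to NIfTI
#' @param series a [dynamic_series()].
#' @param path output path.
#' @export
write_dynamic <- function(series, path) {
  RNifti::writeNifti(as_nifti_image(series$values, series$spacing,
                                    series$affine), path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' Values must be (within `tol`) in {0,1}; anything else is an error, never
#' thresholded silently. If `reference` is given the mask must share its grid.
#'
#' @param path NIfTI path.
#' @param reference optional [volume_grid()] to check geometry against.
#' @param label mask role tag (see [fet_mask()]).
#' @param tol tolerance for recognising 0/1 stored as floats.
#' @return A [fet_mask()].
#' @export
read_mask <- function(path, reference = NULL, label = "generic", tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3-D mask, got ", length(d), " dimensions")
  v <- array(as.numeric(img), d)
  near0 <- abs(v) < tol
  near1 <- abs(v - 1) < tol
  if (!all(near0 | near1))
    stop("mask file is not binary {0,1}: ", path)
  m <- fet_mask(array(as.integer(near1), d),
                spacing = RNifti::pixdim(img)[1:3],
                affine = nifti_affine(img), label = label)
  if (!is.null(reference)) stopifnot_same_grid(m, reference)
  m
}

#' Write a binary mask to NIfTI
#' @param mask a [fet_mask()].
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  RNifti::writeNifti(as_nifti_image(mask$values, mask$spacing, mask$affine),
                     path)
  invisible(path)
}

#' Read a frame schedule from JSON or YAML
#'
#' The file holds a list of `[start_min, end_min]` pairs, e.g.
#' `[[0,5],[5,10],[10,15],[15,20],[20,30],[30,40]]`.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return A [frame_schedule()].
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  frames <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML schedules")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyMatrix = FALSE, simplifyDataFrame = FALSE)
  }
  m <- do.call(rbind, lapply(frames, as.numeric))
  if (is.null(m) || ncol(m) != 2) stop("schedule must be a list of [start_min, end_min] pairs")
  frame_schedule(m[, 1], m[, 2])
}

#' Write a frame schedule to JSON
#' @param schedule a [frame_schedule()].
#' @param path output `.json` path.
#' @export
write_schedule <- function(schedule, path) {
  jsonlite::write_json(
    Map(c, schedule$start_min, schedule$end_min), path,
    auto_unbox = FALSE, digits = NA)
  invisible(path)
}
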