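# Nearest-neighbour resampling of a binary mask under a user-supplied rigid or
# affine transform. Registration itself is never estimated here: inputs are
# assumed pre-registered and the transform, when not identity, comes from an
# external registration step.

#' Resample a mask onto a target grid under a given affine
#'
#' Applies a user-supplied 4x4 world-space transform (mapping mask world
#' coordinates to target world coordinates) and resamples the mask onto the
#' target grid with nearest-neighbour interpolation, which preserves
#' binaryness. Voxels mapping outside the mask's field of view become 0; a
#' fully empty result triggers a warning.
#'
#' @param mask a [fet_mask()].
#' @param target a [volume_grid()] (or mask) defining the output grid.
#' @param transform invertible 4x4 affine in world coordinates; identity by
#'   default.
#' @return A [fet_mask()] on the target grid.
#' @export
apply_affine_resample <- function(mask, target, transform = diag(4)) {
  transform <- as.matrix(transform)
  if (!all(dim(transform) == c(4L, 4L))) stop("'transform' must be 4x4")
  det_t <- det(transform)
  if (!is.finite(det_t) || abs(det_t) < 1e-12)
    stop("singular transform cannot be inverted")

  d_t <- dim(target$values)
  d_m <- dim(mask$values)
  # target voxel (0-based) -> target world -> mask world -> mask voxel
  back <- solve(mask$affine) %*% solve(transform) %*% target$affine

  idx <- as.matrix(expand.grid(x = seq_len(d_t[1]) - 1,
                               y = seq_len(d_t[2]) - 1,
                               z = seq_len(d_t[3]) - 1))
  src <- back %*% rbind(t(idx), 1)
  src <- round(src[1:3, , drop = FALSE])
  inside <- src[1, ] >= 0 & src[1, ] < d_m[1] &
            src[2, ] >= 0 & src[2, ] < d_m[2] &
            src[3, ] >= 0 & src[3, ] < d_m[3]
  out <- integer(nrow(idx))
  lin <- 1 + src[1, inside] + d_m[1] * (src[2, inside] + d_m[2] * src[3, inside])
  out[inside] <- mask$values[lin]
  res <- fet_mask(array(out, d_t), reference = target, label = mask$label)
  if (sum(mask$values) > 0 && sum(res$values) == 0)
    warning("resampled mask is empty: transform maps the mask outside the target field of view")
  res
}
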