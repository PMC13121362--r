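# Dice similarity between the PET segmentation and MRI lesion masks, with the
# evaluability rule: Dice is computed only when both masks are non-empty.

#' Dice similarity coefficient between two masks
#'
#' `DICE = 2|A intersect B| / (|A| + |B|)` on voxel counts (the masks share a
#' grid, so counts and ml volumes are proportional). When either mask is
#' empty the result is marked not evaluable — a tumour without visible
#' uptake, or without a segmentable MRI lesion, is excluded from overlap
#' analysis rather than scored 0.
#'
#' @param a,b [fet_mask()] objects on the same grid.
#' @return A `dice_result`: `dice`, `vol_a_ml`, `vol_b_ml`,
#'   `intersection_ml`, `evaluable`, `reason_not_evaluable`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot_same_grid(a, b)
  na <- sum(a$values); nb <- sum(b$values)
  vox <- voxel_volume_ml(a)
  if (na == 0 || nb == 0) {
    reason <- if (na == 0 && nb == 0) "both masks empty"
              else if (na == 0) "first mask empty" else "second mask empty"
    return(structure(list(dice = NA_real_, vol_a_ml = na * vox,
                          vol_b_ml = nb * vox, intersection_ml = 0,
                          evaluable = FALSE, reason_not_evaluable = reason),
                     class = "dice_result"))
  }
  ni <- sum(a$values & b$values)
  structure(list(dice = 2 * ni / (na + nb), vol_a_ml = na * vox,
                 vol_b_ml = nb * vox, intersection_ml = ni * vox,
                 evaluable = TRUE, reason_not_evaluable = ""),
            class = "dice_result")
}

#' @export
print.dice_result <- function(x, ...) {
  if (x$evaluable)
    cat(sprintf("<dice_result> Dice %.3f (|A| %.3g ml, |B| %.3g ml, A^B %.3g ml)\n",
                x$dice, x$vol_a_ml, x$vol_b_ml, x$intersection_ml))
  else
    cat(sprintf("<dice_result> not evaluable: %s\n", x$reason_not_evaluable))
  invisible(x)
}

#' PET-FLAIR and PET-CE overlap panel
#'
#' Dice of the PET segmentation against the FLAIR hyperintensity mask and,
#' when present, the contrast-enhancing lesion mask. An absent CE mask yields
#' a not-evaluable CE result with reason "no CE lesion".
#'
#' @param pet_seg PET segmentation [fet_mask()].
#' @param flair FLAIR lesion [fet_mask()].
#' @param ce optional contrast-enhancing lesion [fet_mask()].
#' @return List with elements `flair` and `ce`, each a `dice_result`.
#' @export
overlap_panel <- function(pet_seg, flair, ce = NULL) {
  res_flair <- dice_coefficient(pet_seg, flair)
  res_ce <- if (is.null(ce)) {
    structure(list(dice = NA_real_, vol_a_ml = mask_volume_ml(pet_seg),
                   vol_b_ml = NA_real_, intersection_ml = NA_real_,
                   evaluable = FALSE, reason_not_evaluable = "no CE lesion"),
              class = "dice_result")
  } else {
    dice_coefficient(pet_seg, ce)
  }
  list(flair = res_flair, ce = res_ce)
}
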