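# Synthetic phantoms and cohorts with known ground truth. Lesions are hard
# ellipsoids on a homogeneous noisy background; dynamic curves come from three
# kinetic families (increasing / stable / decreasing); MRI companion masks are
# constructed to a target Dice; cohorts are drawn with exact per-stratum
# counts so printed-table structures are reproduced deterministically.
# Every generator is fully deterministic under its seed.

#' Static phantom specification
#'
#' @param grid_shape integer length-3 array shape.
#' @param spacing voxel edge lengths in mm.
#' @param background_mean,background_sd background SUV distribution
#'   (independent Gaussian per voxel; values clamped at 0).
#' @param lesions list of lesions, each a list with `centre` (1-based voxel
#'   index), `semi_axes_mm`, `tbr` (lesion SUV = tbr x background_mean) and
#'   optional `sd` (intra-lesion Gaussian sd).
#' @param seed integer RNG seed; identical seed + spec give bit-identical
#'   phantoms.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(32, 32, 16), spacing = c(2, 2, 2),
                         background_mean = 1.0, background_sd = 0.05,
                         lesions = list(list(centre = c(10, 16, 8),
                                             semi_axes_mm = c(8, 8, 8),
                                             tbr = 2.5, sd = 0)),
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 4),
            all(spacing > 0), background_mean > 0, background_sd >= 0)
  for (l in lesions) {
    stopifnot(all(l$semi_axes_mm > 0), l$tbr > 0)
    if (any(l$centre < 1) || any(l$centre > grid_shape))
      stop("lesion centre lies outside the grid")
  }
  structure(list(grid_shape = as.integer(grid_shape), spacing = spacing,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 lesions = lesions, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a static phantom with ground truth
#'
#' Background voxels are drawn around `background_mean`; lesion voxels are set
#' to `tbr x background_mean` plus optional intra-lesion noise. Returns the
#' volume together with the ground-truth lesion mask and a mirrored
#' contralateral background ROI (an error if that ROI would overlap a
#' lesion — then supply your own).
#'
#' @param spec a [phantom_spec()].
#' @return List: `volume` ([volume_grid()]), `lesion_mask`, `background_mask`
#'   (both [fet_mask()]), and `spec`.
#' @export
make_static_phantom <- function(spec) {
  set.seed(spec$seed)
  d <- spec$grid_shape
  vals <- array(stats::rnorm(prod(d), spec$background_mean, spec$background_sd), d)
  lesion <- array(0L, d)
  for (l in spec$lesions) {
    e <- ellipsoid_mask_values(d, spec$spacing, l$centre, l$semi_axes_mm)
    sdl <- if (is.null(l$sd)) 0 else l$sd
    vals[e > 0] <- l$tbr * spec$background_mean +
      stats::rnorm(sum(e), 0, sdl)
    lesion[e > 0] <- 1L
  }
  vals <- pmax(vals, 0)
  vol <- volume_grid(vals, spacing = spec$spacing)
  bg <- mirrored_background_roi(vol, spec$lesions[[1]]$centre,
                                spec$lesions[[1]]$semi_axes_mm)
  if (any(bg$values & lesion))
    stop("mirrored background ROI overlaps a lesion; use an off-midline lesion centre")
  if (sum(bg$values) == 0)
    stop("mirrored background ROI is empty on this grid")
  list(volume = vol,
       lesion_mask = fet_mask(lesion, reference = vol, label = "generic"),
       background_mask = bg,
       spec = spec)
}

#' Dynamic TAC specification
#'
#' @param schedule a [frame_schedule()] (default [default_schedule()]).
#' @param curve_family `"increasing"`, `"stable"` or `"decreasing"`.
#' @param peak_time_min nominal peak mid-time (stable/decreasing families);
#'   must equal one of the schedule mid-times.
#' @param tau_min saturation time constant of the increasing family.
#' @param decline_frac total relative post-peak decline of the decreasing
#'   family by scan end (>= 0.15 so the class is unambiguous).
#' @param noise_sd_rel Gaussian noise sd relative to the peak value.
#' @param seed integer RNG seed.
#' @return A `dynamic_spec` list.
#' @export
dynamic_spec <- function(schedule = default_schedule(),
                         curve_family = c("increasing", "stable", "decreasing"),
                         peak_time_min = 12.5, tau_min = 10,
                         decline_frac = 0.25, noise_sd_rel = 0, seed = 1L) {
  curve_family <- match.arg(curve_family)
  stopifnot(noise_sd_rel >= 0, tau_min > 0)
  if (curve_family == "decreasing" && decline_frac < 0.15)
    stop("'decline_frac' must be >= 0.15 for an unambiguous decreasing curve")
  if (curve_family %in% c("stable", "decreasing")) {
    if (!any(abs(schedule$mid_min - peak_time_min) < 1e-9))
      stop("'peak_time_min' must coincide with a schedule frame mid-time")
    if (curve_family == "decreasing" &&
        peak_time_min >= schedule$mid_min[length(schedule)])
      stop("a decreasing curve needs frames after the peak")
  }
  structure(list(schedule = schedule, curve_family = curve_family,
                 peak_time_min = peak_time_min, tau_min = tau_min,
                 decline_frac = decline_frac, noise_sd_rel = noise_sd_rel,
                 seed = as.integer(seed)),
            class = "dynamic_spec")
}

# nominal unit-peak curve of a kinetic family at the schedule mid-times
family_curve <- function(dyn) {
  t <- dyn$schedule$mid_min
  switch(dyn$curve_family,
    increasing = {
      v <- 1 - exp(-t / dyn$tau_min)
      v / v[length(v)]                       # strictly rising, peak at end
    },
    decreasing = {
      p <- which(abs(t - dyn$peak_time_min) < 1e-9)
      v <- numeric(length(t))
      if (p > 1) v[1:p] <- seq(0.6, 1, length.out = p) else v[1] <- 1
      v[p:length(t)] <- seq(1, 1 - dyn$decline_frac,
                            length.out = length(t) - p + 1)
      v
    },
    stable = {
      p <- which(abs(t - dyn$peak_time_min) < 1e-9)
      v <- rep(0.99, length(t))              # flat within 1% of the peak
      v[p] <- 1                              # unique max at the peak frame
      v
    })
}

# ground-truth TTP of the nominal curve
family_ttp <- function(dyn) {
  t <- dyn$schedule$mid_min
  if (dyn$curve_family == "increasing") t[length(t)] else dyn$peak_time_min
}

#' Generate synthetic time-activity curves with known class
#'
#' Draws `n` TACs from one kinetic family at the given relative noise level —
#' the unit for classifier-recovery experiments.
#'
#' @param dyn a [dynamic_spec()]; its `noise_sd_rel` and `seed` are used.
#' @param n number of curves.
#' @param peak_suv peak SUV scaling (class is scale-invariant).
#' @return List: `curves` (list of `tac`), `true_class`, `true_ttp`.
#' @export
make_tacs <- function(dyn, n = 1L, peak_suv = 2.5) {
  set.seed(dyn$seed)
  base <- family_curve(dyn) * peak_suv
  curves <- lapply(seq_len(n), function(i) {
    v <- base + stats::rnorm(length(base), 0, dyn$noise_sd_rel * peak_suv)
    new_tac(dyn$schedule$mid_min, pmax(v, 0), "whole_roi", NA_integer_)
  })
  list(curves = curves, true_class = dyn$curve_family,
       true_ttp = family_ttp(dyn))
}

#' Generate a dynamic phantom with ground truth
#'
#' Lesion voxels follow the family curve scaled so its peak equals
#' `tbr x background_mean`; background voxels stay flat at the background
#' mean. Per-voxel, per-frame Gaussian noise is added at `noise_sd_rel` of
#' the lesion peak (0 = noiseless, making all downstream kinetics exactly
#' invertible).
#'
#' @param phantom a [phantom_spec()] (its first lesion defines the tumour).
#' @param dyn a [dynamic_spec()].
#' @return List: `series` ([dynamic_series()]), `lesion_mask`,
#'   `background_mask`, `true_class`, `true_ttp`.
#' @export
make_dynamic_phantom <- function(phantom, dyn) {
  static <- make_static_phantom(phantom)     # geometry + masks (seeded)
  set.seed(dyn$seed)
  d <- phantom$grid_shape
  nf <- length(dyn$schedule)
  base <- family_curve(dyn)
  lesion <- static$lesion_mask$values > 0
  peak_suv <- phantom$lesions[[1]]$tbr * phantom$background_mean
  vals <- array(0, c(d, nf))
  for (k in seq_len(nf)) {
    fr <- array(phantom$background_mean, d)
    fr[lesion] <- base[k] * peak_suv
    if (dyn$noise_sd_rel > 0)
      fr <- fr + array(stats::rnorm(prod(d), 0, dyn$noise_sd_rel * peak_suv), d)
    vals[, , , k] <- pmax(fr, 0)
  }
  list(series = dynamic_series(vals, dyn$schedule, spacing = phantom$spacing),
       lesion_mask = static$lesion_mask,
       background_mask = static$background_mask,
       true_class = dyn$curve_family,
       true_ttp = family_ttp(dyn))
}

#' Construct a companion mask with a target Dice
#'
#' Builds a mask B from a non-empty reference A such that
#' `dice(A, B) = round(target x |A|) / |A|`, within 1/(2|A|) of the target:
#' B keeps the `k` reference voxels closest to the reference centroid and
#' adds `|A| - k` outside voxels nearest the centroid (the shell around the
#' lesion), so `|B| = |A|`. Target 1 returns a copy; target 0 a disjoint
#' shell mask. Deterministic; the seed only breaks distance ties.
#'
#' @param reference non-empty [fet_mask()].
#' @param target_dice target Dice in `[0, 1]`.
#' @param seed integer seed for tie-breaking.
#' @return A [fet_mask()] on the reference grid.
#' @export
make_mask_pair <- function(reference, target_dice, seed = 1L) {
  stopifnot(target_dice >= 0, target_dice <= 1)
  n_a <- sum(reference$values)
  if (n_a == 0) stop("reference mask is empty")
  d <- dim(reference$values)
  if (abs(target_dice - 1) < 1e-12)
    return(fet_mask(reference$values, reference = reference,
                    label = reference$label))
  set.seed(seed)
  k <- round(target_dice * n_a)
  m <- n_a - k
  a_idx <- which(reference$values > 0, arr.ind = TRUE)
  centroid <- colMeans(a_idx)
  sp <- reference$spacing

  dist_mm2 <- function(idx) {
    dd <- sweep(idx, 2, centroid) %*% diag(sp)
    rowSums(dd^2) + stats::runif(nrow(idx), 0, 1e-6)   # seeded tie-break
  }
  out <- array(0L, d)
  if (k > 0) {
    keep <- a_idx[order(dist_mm2(a_idx))[seq_len(k)], , drop = FALSE]
    out[keep] <- 1L
  }
  if (m > 0) {
    b_idx <- which(reference$values == 0, arr.ind = TRUE)
    if (nrow(b_idx) < m)
      stop("target Dice unreachable: not enough voxels outside the reference")
    add <- b_idx[order(dist_mm2(b_idx))[seq_len(m)], , drop = FALSE]
    out[add] <- 1L
  }
  fet_mask(out, reference = reference, label = reference$label)
}

# length-safe shuffle (sample(x) misbehaves on length-1 numeric vectors)
shuffle <- function(x) x[sample.int(length(x))]

# largest-remainder rounding of n * freq to integer counts summing to n
exact_counts <- function(freq, n) {
  raw <- freq * n
  base <- floor(raw + 1e-9)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Cohort specification
#'
#' A stratified generator spec: one row per (histology x WHO grade) stratum
#' with the stratum size and the per-stratum frequencies of contrast
#' enhancement, PET positivity, dynamic availability, kinetic class and
#' TTP_min level, plus TBR and Dice distribution parameters. In exact-count
#' mode (default) `frequency x n` values are converted to integer counts by
#' largest-remainder rounding, so marginal tables are reproduced
#' deterministically.
#'
#' @param strata data.frame with columns `histology`, `who_grade`, `n`,
#'   `p_ce`, `p_pos`, `p_dyn` (dynamic availability, a subset of the
#'   positives), `p_inc`, `p_stable`, `p_dec` (kinetic classes among
#'   dynamic), `p_ttp_12.5`, `p_ttp_17.5`, `p_ttp_25`, `p_ttp_35` (TTP_min
#'   levels among dynamic), `tbr_meanlog`, `tbr_sdlog` (log-normal offset
#'   above the 1.6 positivity threshold for positive tumours),
#'   `dice_flair`, `dice_ce` (target medians).
#' @param seed integer RNG seed.
#' @param exact logical; exact-count mode (TRUE) vs multinomial sampling.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(strata, seed = 1L, exact = TRUE) {
  needed <- c("histology", "who_grade", "n", "p_ce", "p_pos", "p_dyn",
              "p_inc", "p_stable", "p_dec",
              "p_ttp_12.5", "p_ttp_17.5", "p_ttp_25", "p_ttp_35",
              "tbr_meanlog", "tbr_sdlog", "dice_flair", "dice_ce")
  missing_cols <- setdiff(needed, names(strata))
  if (length(missing_cols))
    stop("missing strata column(s): ", paste(missing_cols, collapse = ", "))
  pcols <- grep("^p_", needed, value = TRUE)
  if (any(strata[pcols] < 0) || any(strata[pcols] > 1))
    stop("frequencies must lie in [0, 1]")
  if (any(abs(strata$p_inc + strata$p_stable + strata$p_dec - 1) > 1e-9 &
          strata$p_dyn > 0))
    stop("kinetic class frequencies must sum to 1 in strata with dynamic data")
  structure(list(strata = strata, seed = as.integer(seed), exact = exact),
            class = "cohort_spec")
}

#' Default glioma cohort specification
#'
#' Stratum sizes and frequencies emulating a published single-centre
#' IDH-mutant glioma cohort (147 patients: 79 astrocytomas of WHO grades
#' 2/3/4 = 49/21/9, 68 oligodendrogliomas of grades 2/3 = 52/16), including
#' its per-grade contrast-enhancement rates, PET-positivity rates (62/68
#' oligodendrogliomas, 35/79 astrocytomas), dynamic availability (91 of the
#' 97 positives), the kinetic-class margins by grade (41,13,5 / 13,9,4 /
#' 2,0,4) and by histology (24,5,4 / 32,17,9), and TTP_min levels clustering
#' WHO grade 4 astrocytomas at 12.5 min. The joint class split across
#' strata is one consistent completion of the two published margins; the
#' per-grade positivity split within astrocytomas is a plausible default
#' (only the overall 35/79 is constrained).
#'
#' @param seed integer RNG seed.
#' @return A `cohort_spec` for [make_cohort()].
#' @export
glioma_cohort_spec <- function(seed = 1L) {
  s <- data.frame(
    histology = c("astrocytoma", "astrocytoma", "astrocytoma",
                  "oligodendroglioma", "oligodendroglioma"),
    who_grade = c(2L, 3L, 4L, 2L, 3L),
    n     = c(49, 21, 9, 52, 16),
    n_ce  = c(10, 6, 8, 10, 10),
    n_pos = c(17, 12, 6, 46, 16),
    n_dyn = c(17, 10, 6, 42, 16),
    n_inc = c(17, 5, 2, 24, 8),
    n_sta = c(0, 5, 0, 13, 4),
    n_dec = c(0, 0, 4, 5, 4),
    n_t12 = c(0, 0, 4, 0, 2),
    n_t17 = c(1, 1, 1, 2, 3),
    n_t25 = c(3, 2, 1, 10, 6),
    n_t35 = c(13, 7, 0, 30, 5),
    tbr_meanlog = log(c(0.4, 0.6, 1.5, 0.85, 1.1)),
    tbr_sdlog = rep(0.6, 5),
    dice_flair = c(0.33, 0.31, 0.71, 0.63, 0.77),
    dice_ce = c(0.14, 0.21, 0.61, 0.08, 0.20),
    stringsAsFactors = FALSE)
  strata <- data.frame(
    histology = s$histology, who_grade = s$who_grade, n = s$n,
    p_ce = s$n_ce / s$n, p_pos = s$n_pos / s$n, p_dyn = s$n_dyn / s$n,
    p_inc = s$n_inc / s$n_dyn, p_stable = s$n_sta / s$n_dyn,
    p_dec = s$n_dec / s$n_dyn,
    `p_ttp_12.5` = s$n_t12 / s$n_dyn, `p_ttp_17.5` = s$n_t17 / s$n_dyn,
    p_ttp_25 = s$n_t25 / s$n_dyn, p_ttp_35 = s$n_t35 / s$n_dyn,
    tbr_meanlog = s$tbr_meanlog, tbr_sdlog = s$tbr_sdlog,
    dice_flair = s$dice_flair, dice_ce = s$dice_ce,
    check.names = FALSE, stringsAsFactors = FALSE)
  cohort_spec(strata, seed = seed)
}

#' Generate a synthetic patient cohort
#'
#' Draws one record per patient per stratum. In exact-count mode categorical
#' fields are assigned by deterministic counts (largest-remainder rounding of
#' `frequency x n`) permuted within the stratum; continuous fields (TBR, PET
#' volume, Dice) are drawn from the stratum's distribution parameters.
#' Dynamic fields are assigned only to PET-positive patients (an error if a
#' stratum requests more dynamic patients than positives); Dice values exist
#' only where the PET lesion is measurable, and CE Dice additionally requires
#' contrast enhancement.
#'
#' @param spec a [cohort_spec()].
#' @return A validated patient-record data.frame (see
#'   [validate_patient_records()]).
#' @export
make_cohort <- function(spec) {
  set.seed(spec$seed)
  ttp_levels <- c(12.5, 17.5, 25, 35)
  rows <- lapply(seq_len(nrow(spec$strata)), function(i) {
    st <- spec$strata[i, ]
    n <- st$n
    draw_flags <- function(p) {
      if (spec$exact) {
        cnt <- exact_counts(c(p, 1 - p), n)[1]
        shuffle(rep(c(TRUE, FALSE), c(cnt, n - cnt)))
      } else stats::runif(n) < p
    }
    pos <- draw_flags(st$p_pos)
    ce <- draw_flags(st$p_ce)
    n_pos <- sum(pos)
    n_dyn <- if (spec$exact) exact_counts(c(st$p_dyn, 1 - st$p_dyn), n)[1]
             else stats::rbinom(1, n_pos, min(1, st$p_dyn * n / max(n_pos, 1)))
    if (n_dyn > n_pos)
      stop(sprintf("stratum %s grade %d: %d dynamic patients requested but only %d PET-positive",
                   st$histology, st$who_grade, n_dyn, n_pos))
    dyn <- rep(FALSE, n)
    dyn[shuffle(which(pos))[seq_len(n_dyn)]] <- TRUE

    cls <- rep(NA_character_, n)
    tmin <- rep(NA_real_, n)
    if (n_dyn > 0) {
      cls_counts <- exact_counts(c(st$p_inc, st$p_stable, st$p_dec), n_dyn)
      cls[dyn] <- shuffle(rep(c("increasing", "stable", "decreasing"), cls_counts))
      ttp_counts <- exact_counts(unlist(st[paste0("p_ttp_", c("12.5", "17.5", "25", "35"))]),
                                 n_dyn)
      tmin[dyn] <- shuffle(rep(ttp_levels, ttp_counts))
    }

    tbr_max <- ifelse(pos,
                      1.6 + stats::rlnorm(n, st$tbr_meanlog, st$tbr_sdlog),
                      stats::runif(n, 1.0, 1.6 - 1e-6))
    tbr_mean <- 1 + (tbr_max - 1) * stats::runif(n, 0.5, 0.8)
    pet_vol <- ifelse(pos, stats::rlnorm(n, log(5), 0.9), 0)

    clamp01 <- function(x) pmin(pmax(x, 0.01), 0.99)
    dice_flair <- ifelse(pos, clamp01(stats::rnorm(n, st$dice_flair, 0.05)),
                         NA_real_)
    dice_ce <- ifelse(pos & ce, clamp01(stats::rnorm(n, st$dice_ce, 0.05)),
                      NA_real_)

    data.frame(
      patient_id = sprintf("%s_g%d_%03d", substr(st$histology, 1, 5),
                           st$who_grade, seq_len(n)),
      histology = st$histology, who_grade = st$who_grade,
      ce_present = ce, pet_positive = pos,
      tbr_max = tbr_max, tbr_mean = tbr_mean, pet_volume_ml = pet_vol,
      curve_class = cls, ttp_min = tmin,
      dice_flair = dice_flair, dice_ce = dice_ce,
      stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  rownames(rec) <- NULL
  validate_patient_records(rec)
  rec
}
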