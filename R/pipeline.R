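# Per-patient and cohort orchestration: background -> segmentation -> uptake
# metrics -> (optional) dynamic kinetics -> (optional) Dice overlap, with
# per-patient failure isolation, provenance (input checksums, config hash)
# and deterministic outputs.

#' Run configuration
#'
#' @param manifest data.frame with one row per patient and columns
#'   `patient_id`, `pet`, `background_mask`, and optionally `flair`, `ce`,
#'   `dynamic`, `schedule`, `histology`, `who_grade` (NA where absent). Paths
#'   are checked at validation time. `pet` may be NA when `dynamic` is given:
#'   the static volume is then the 20-40 min summation of the dynamic series.
#' @param segmentation a [segmentation_config()].
#' @param kinetics a [kinetic_config()].
#' @param analyses subset of `c("static", "dynamic", "dice")`; `"static"` is
#'   always run.
#' @param static_window static summation window in minutes (used when the
#'   static volume is derived from a dynamic series).
#' @param isocontour_window summation window for the kinetic isocontour ROI.
#' @param out_dir optional output directory for JSON reports and CSV tables.
#' @param bg_min_voxels minimum background-ROI size.
#' @param seed integer seed recorded in reports (the analysis itself is
#'   deterministic).
#' @return A `run_config` list.
#' @export
run_config <- function(manifest, segmentation = segmentation_config(),
                       kinetics = kinetic_config(),
                       analyses = c("static", "dynamic", "dice"),
                       static_window = c(20, 40),
                       isocontour_window = c(10, 30),
                       out_dir = NULL, bg_min_voxels = 100L, seed = 1L) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  needed <- c("patient_id", "pet", "background_mask")
  missing_cols <- setdiff(needed, names(manifest))
  if (length(missing_cols))
    stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "))
  for (col in c("flair", "ce", "dynamic", "schedule", "histology", "who_grade"))
    if (!col %in% names(manifest)) manifest[[col]] <- NA
  if (anyDuplicated(manifest$patient_id)) stop("duplicate patient_id in manifest")
  path_cols <- c("pet", "background_mask", "flair", "ce", "dynamic", "schedule")
  for (col in path_cols) {
    p <- manifest[[col]]
    bad <- !is.na(p) & !file.exists(p)
    if (any(bad))
      stop("manifest references missing file(s): ",
           paste(p[bad], collapse = ", "))
  }
  structure(list(manifest = manifest, segmentation = segmentation,
                 kinetics = kinetics, analyses = analyses,
                 static_window = static_window,
                 isocontour_window = isocontour_window,
                 out_dir = out_dir, bg_min_voxels = as.integer(bg_min_voxels),
                 seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(
    config[c("segmentation", "kinetics", "analyses", "static_window",
             "isocontour_window", "bg_min_voxels", "seed")])), f)
  unname(tools::md5sum(f))
}

input_checksums <- function(entry) {
  paths <- unlist(entry[c("pet", "background_mask", "flair", "ce",
                          "dynamic", "schedule")])
  paths <- paths[!is.na(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the full analysis for one patient
#'
#' Executes background estimation, threshold segmentation, uptake metrics,
#' then (per the configured analyses and available inputs) dynamic kinetics
#' and PET-MRI Dice overlap. Any error is captured and returned as a failure
#' entry rather than propagated, so a corrupt input never aborts a batch.
#'
#' @param config a [run_config()].
#' @param entry one manifest row (data.frame or list).
#' @return A `patient_report` list: `ok`, `record` (one patient-record row,
#'   NULL on failure), `report` (full per-stage results + provenance),
#'   `error` (message on failure).
#' @export
run_patient <- function(config, entry) {
  pid <- as.character(entry$patient_id)
  res <- try({
    dyn_series <- NULL
    if (!is.na(entry$dynamic)) {
      if (is.na(entry$schedule))
        stop("dynamic series given without a frame schedule")
      dyn_series <- read_dynamic(entry$dynamic, read_schedule(entry$schedule))
    }
    vol <- if (!is.na(entry$pet)) read_volume(entry$pet) else {
      if (is.null(dyn_series))
        stop("neither a static PET volume nor a dynamic series was supplied")
      summation_image(dyn_series, config$static_window[1], config$static_window[2])
    }
    bg_roi <- read_mask(entry$background_mask, reference = vol,
                        label = "background_roi")
    bg <- estimate_background(vol, bg_roi, min_voxels = config$bg_min_voxels)
    seg <- segment_lesion(vol, bg, config$segmentation)
    metrics <- compute_uptake_metrics(vol, seg$mask, bg)

    report <- list(patient_id = pid,
                   background = unclass(bg),
                   threshold_suv = seg$threshold_suv,
                   n_components_removed = seg$n_components_removed,
                   metrics = unclass(metrics))

    record <- data.frame(
      patient_id = pid,
      histology = if (is.na(entry$histology)) NA_character_ else as.character(entry$histology),
      who_grade = if (is.na(entry$who_grade)) NA_integer_ else as.integer(entry$who_grade),
      ce_present = !is.na(entry$ce),
      pet_positive = metrics$pet_positive,
      tbr_max = metrics$tbr_max, tbr_mean = metrics$tbr_mean,
      pet_volume_ml = metrics$pet_volume_ml,
      curve_class = NA_character_, ttp_min = NA_real_,
      dice_flair = NA_real_, dice_ce = NA_real_,
      stringsAsFactors = FALSE)

    if ("dynamic" %in% config$analyses && !is.null(dyn_series)) {
      summ <- summation_image(dyn_series, config$isocontour_window[1],
                              config$isocontour_window[2])
      search <- if (sum(seg$mask$values) > 0) seg$mask else NULL
      roi <- isocontour_roi(summ, config$kinetics$isocontour_fraction, search)
      whole <- extract_tac(dyn_series, roi)
      slices <- extract_slice_tacs(dyn_series, roi,
                                   config$kinetics$min_slice_voxels)
      if (length(slices) == 0) slices <- list(whole)
      kin <- classify_tumour_kinetics(slices, whole, config$kinetics)
      record$curve_class <- kin$curve_class
      record$ttp_min <- kin$ttp_min
      report$kinetics <- list(
        curve_class = kin$curve_class,
        whole_roi_class = kin$whole_roi_class,
        per_slice_classes = kin$per_slice_classes,
        ttp_per_slice = as.list(kin$ttp_per_slice),
        ttp_min = kin$ttp_min,
        ttp_min_fallback = kin$ttp_min_fallback,
        n_slices_skipped = attr(slices, "n_skipped"),
        evidence = kin$evidence)
    }

    if ("dice" %in% config$analyses && !is.na(entry$flair)) {
      flair <- read_mask(entry$flair, reference = vol, label = "flair")
      ce <- if (!is.na(entry$ce)) read_mask(entry$ce, reference = vol,
                                            label = "ce") else NULL
      panel <- overlap_panel(seg$mask, flair, ce)
      record$dice_flair <- panel$flair$dice
      record$dice_ce <- panel$ce$dice
      report$dice <- list(flair = unclass(panel$flair),
                          ce = unclass(panel$ce))
    }

    report$provenance <- list(config_hash = config_hash(config),
                              package_version = as.character(utils::packageVersion("fetquant")),
                              inputs = input_checksums(entry),
                              seed = config$seed)
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(report,
                           file.path(config$out_dir, paste0(pid, ".json")),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           na = "null", force = TRUE)
    }
    list(ok = TRUE, record = record, report = report, error = NULL)
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    return(structure(list(ok = FALSE, record = NULL, report = NULL,
                          error = conditionMessage(attr(res, "condition")),
                          patient_id = pid),
                     class = "patient_report"))
  structure(res, class = "patient_report")
}

#' Run a cohort and assemble summaries and tests
#'
#' Runs every manifest patient (continue-on-error), binds the successful
#' records, and computes the cohort summary tables (TBR, PET volume, Dice by
#' histology and grade; positivity and kinetic-class counts) and the test
#' battery (kinetic class x grade and x histology chi-square, TBR and Dice
#' Mann-Whitney comparisons between histologies) with per-analysis
#' denominators and exclusion counts. No multiplicity correction is applied.
#'
#' @param config a [run_config()].
#' @return A `cohort_result`: `records`, `failures`, `summaries` (list of
#'   data.frames), `tests` (list of `fet_test_result`), `denominators`.
#' @export
run_cohort <- function(config) {
  results <- lapply(seq_len(nrow(config$manifest)), function(i)
    run_patient(config, config$manifest[i, ]))
  ok <- vapply(results, function(r) isTRUE(r$ok), logical(1))
  failures <- lapply(results[!ok], function(r)
    list(patient_id = r$patient_id, error = r$error))
  if (!any(ok)) stop("no patient completed successfully")
  records <- do.call(rbind, lapply(results[ok], `[[`, "record"))
  out <- cohort_analysis(records)
  out$failures <- failures
  out$config_hash <- config_hash(config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(config$out_dir, "records.csv"),
                     row.names = FALSE)
    for (nm in names(out$summaries))
      utils::write.csv(out$summaries[[nm]],
                       file.path(config$out_dir, paste0("summary_", nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(
      lapply(out$tests, unclass),
      file.path(config$out_dir, "tests.json"),
      auto_unbox = TRUE, digits = NA, na = "null", force = TRUE)
  }
  out
}

#' Cohort statistics from an assembled record table
#'
#' The statistics layer of [run_cohort()], usable directly on any validated
#' patient-record table (e.g. from [make_cohort()] or
#' [read_patient_records()]).
#'
#' @param records validated patient-record data.frame.
#' @return A `cohort_result` list (see [run_cohort()]).
#' @export
cohort_analysis <- function(records) {
  validate_patient_records(records)
  has_strata <- !anyNA(records$histology) && !anyNA(records$who_grade)
  summaries <- list(
    tbr_max = summarize_cohort(records, "tbr_max",
                               if (has_strata) c("histology", "who_grade")),
    pet_positive = summarize_cohort(records, "pet_positive",
                                    if (has_strata) "histology"),
    dice_flair = summarize_cohort(records, "dice_flair",
                                  if (has_strata) c("histology", "who_grade")),
    dice_ce = summarize_cohort(records, "dice_ce",
                               if (has_strata) c("histology", "who_grade")),
    ttp_min = summarize_cohort(records, "ttp_min",
                               if (has_strata) c("histology", "who_grade")))

  tests <- list()
  denominators <- list(n_total = nrow(records),
                       n_pet_positive = sum(records$pet_positive),
                       n_dynamic = sum(!is.na(records$curve_class)),
                       n_dice_flair = sum(!is.na(records$dice_flair)),
                       n_dice_ce = sum(!is.na(records$dice_ce)))

  dyn <- records[!is.na(records$curve_class), ]
  if (has_strata && nrow(dyn) > 0) {
    tab_grade <- table(factor(dyn$who_grade),
                       factor(dyn$curve_class,
                              levels = c("increasing", "stable", "decreasing")))
    tab_grade <- tab_grade[rowSums(tab_grade) > 0, colSums(tab_grade) > 0,
                           drop = FALSE]
    if (nrow(tab_grade) >= 2 && ncol(tab_grade) >= 2)
      tests$kinetics_by_grade <- chi_square(unclass(tab_grade))
    tab_hist <- table(factor(dyn$histology),
                      factor(dyn$curve_class,
                             levels = c("increasing", "stable", "decreasing")))
    tab_hist <- tab_hist[rowSums(tab_hist) > 0, colSums(tab_hist) > 0,
                         drop = FALSE]
    if (nrow(tab_hist) >= 2 && ncol(tab_hist) >= 2)
      tests$kinetics_by_histology <- chi_square(unclass(tab_hist))
  }
  if (has_strata && length(unique(records$histology)) == 2) {
    split_h <- split(records$tbr_max, records$histology)
    tests$tbr_max_by_histology <- mann_whitney_u(split_h[[1]], split_h[[2]])
    df_ok <- records[!is.na(records$dice_flair), ]
    if (length(unique(df_ok$histology)) == 2) {
      split_d <- split(df_ok$dice_flair, df_ok$histology)
      tests$dice_flair_by_histology <- mann_whitney_u(split_d[[1]], split_d[[2]])
    }
    tt_ok <- records[!is.na(records$ttp_min), ]
    if (length(unique(tt_ok$histology)) == 2) {
      split_t <- split(tt_ok$ttp_min, tt_ok$histology)
      tests$ttp_min_by_histology <- mann_whitney_u(split_t[[1]], split_t[[2]])
    }
  }
  structure(list(records = records, summaries = summaries, tests = tests,
                 denominators = denominators, failures = list()),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  d <- x$denominators
  cat(sprintf("<cohort_result> %d patients (%d PET-positive, %d with dynamic data), %d failure(s)\n",
              d$n_total, d$n_pet_positive, d$n_dynamic, length(x$failures)))
  for (nm in names(x$tests)) { cat(" ", nm, ": "); print(x$tests[[nm]]) }
  invisible(x)
}

#' Write a synthetic patient's files to disk
#'
#' Generates one phantom patient (static PET, mirrored background ROI, FLAIR
#' and optional CE masks built to target Dice values, and — for PET-positive
#' patients — a dynamic series of the requested kinetic family with its
#' schedule) and writes everything as NIfTI/JSON under `dir`. Used to build
#' end-to-end test cohorts and by the simulate CLI.
#'
#' @param dir output directory (created if needed).
#' @param patient_id identifier used in file names.
#' @param tbr lesion-to-background ratio of the static lesion.
#' @param family kinetic family (NA skips the dynamic series).
#' @param peak_time_min nominal TTP for stable/decreasing families.
#' @param dice_flair,dice_ce target Dice of the MRI masks (NA skips CE).
#' @param grid_shape,spacing phantom geometry.
#' @param noise_sd background/lesion noise sd (0 = noiseless).
#' @param seed integer seed.
#' @return Named list: manifest row (`entry`) and ground truth (`truth`).
#' @export
write_phantom_patient <- function(dir, patient_id, tbr = 2.5,
                                  family = "increasing", peak_time_min = 12.5,
                                  dice_flair = 0.6, dice_ce = NA,
                                  grid_shape = c(24, 24, 12),
                                  spacing = c(2, 2, 2), noise_sd = 0,
                                  seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  centre <- c(round(grid_shape[1] * 0.3), round(grid_shape[2] / 2),
              round(grid_shape[3] / 2))
  ps <- phantom_spec(grid_shape = grid_shape, spacing = spacing,
                     background_mean = 1.0, background_sd = noise_sd,
                     lesions = list(list(centre = centre,
                                         semi_axes_mm = c(8, 8, 8),
                                         tbr = tbr, sd = noise_sd)),
                     seed = seed)
  ph <- make_static_phantom(ps)
  p <- function(suffix) file.path(dir, paste0(patient_id, "_", suffix))
  write_volume(ph$volume, p("pet.nii.gz"))
  write_mask(ph$background_mask, p("bg.nii.gz"))
  flair <- make_mask_pair(ph$lesion_mask, dice_flair, seed = seed + 1L)
  write_mask(flair, p("flair.nii.gz"))
  ce_path <- NA_character_
  if (!is.na(dice_ce)) {
    ce <- make_mask_pair(ph$lesion_mask, dice_ce, seed = seed + 2L)
    write_mask(ce, p("ce.nii.gz"))
    ce_path <- p("ce.nii.gz")
  }
  dyn_path <- NA_character_; sched_path <- NA_character_
  true_class <- NA_character_; true_ttp <- NA_real_
  if (!is.na(family)) {
    ds <- dynamic_spec(curve_family = family, peak_time_min = peak_time_min,
                       noise_sd_rel = noise_sd, seed = seed + 3L)
    dp <- make_dynamic_phantom(ps, ds)
    write_dynamic(dp$series, p("dyn.nii.gz"))
    write_schedule(ds$schedule, p("schedule.json"))
    dyn_path <- p("dyn.nii.gz"); sched_path <- p("schedule.json")
    true_class <- dp$true_class; true_ttp <- dp$true_ttp
  }
  measured_flair <- dice_coefficient(ph$lesion_mask, flair)
  list(entry = data.frame(patient_id = patient_id, pet = p("pet.nii.gz"),
                          background_mask = p("bg.nii.gz"),
                          flair = p("flair.nii.gz"), ce = ce_path,
                          dynamic = dyn_path, schedule = sched_path,
                          histology = NA, who_grade = NA,
                          stringsAsFactors = FALSE),
       truth = list(pet_positive = tbr >= 1.6, tbr = tbr,
                    lesion_voxels = sum(ph$lesion_mask$values),
                    dice_flair = measured_flair$dice,
                    dice_ce = dice_ce,
                    curve_class = true_class, ttp_min = true_ttp))
}
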