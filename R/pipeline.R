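# End-to-end pipeline: per-subject processing (orient, crop, segment, repair,
# measure, pair) and cohort batch runs with tabular CSV outputs. A pipeline
# configuration captures every processing parameter and round-trips through
# YAML so runs are reproducible from a single text file.

#' Pipeline configuration
#'
#' All parameters of the subject-processing pipeline in one object. The same
#' configuration (in particular the same crop planes) is applied to both
#' repeated scans of a subject.
#'
#' @param crop A [crop_config()].
#' @param repair A [repair_params()].
#' @param orient Run the automatic orientation stage (default `TRUE`; set
#'   `FALSE` for scans already in the canonical frame).
#' @param orient_seed Seed for the support-plane consensus draws.
#' @param inlier_tol Support-plane inlier tolerance, mm.
#' @param facing `"pca_torso"` or `"manual"` (see [face_frontal()]).
#' @param manual_angle Facing angle (degrees) in manual mode.
#' @param min_faces Debris threshold for leg components.
#' @param midline_delta Midline tolerance for visibility classification, mm.
#' @return A list of class `legvol_config`.
#' @export
pipeline_config <- function(crop = crop_config(70, 810), repair = repair_params(),
                            orient = TRUE, orient_seed = 1, inlier_tol = 1,
                            facing = c("pca_torso", "manual"), manual_angle = 0,
                            min_faces = 100, midline_delta = 2) {
  facing <- match.arg(facing)
  stopifnot(inherits(crop, "legvol_crop"), is.logical(orient))
  structure(list(crop = crop, repair = repair, orient = orient,
                 orient_seed = orient_seed, inlier_tol = inlier_tol,
                 facing = facing, manual_angle = manual_angle,
                 min_faces = min_faces, midline_delta = midline_delta),
            class = "legvol_config")
}

#' Read and write pipeline configurations
#'
#' YAML round-trip of a [pipeline_config()].
#'
#' @param path YAML file path.
#' @param config A `legvol_config`.
#' @return `read_pipeline_config()` returns a `legvol_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) legvol_abort(paste0("no such file: ", path),
                                       "legvol_io_error")
  y <- yaml::read_yaml(path)
  pipeline_config(
    crop = do.call(crop_config, y$crop),
    repair = do.call(repair_params, y$repair),
    orient = y$orient %||% TRUE,
    orient_seed = y$orient_seed %||% 1,
    inlier_tol = y$inlier_tol %||% 1,
    facing = y$facing %||% "pca_torso",
    manual_angle = y$manual_angle %||% 0,
    min_faces = y$min_faces %||% 100,
    midline_delta = y$midline_delta %||% 2)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "legvol_config"))
  y <- unclass(config)
  y$crop <- unclass(y$crop)
  y$repair <- unclass(y$repair)
  yaml::write_yaml(y, path)
  invisible(path)
}

# One scan: orient (optional), crop, extract components, classify visibility,
# return repaired left/right leg_segments plus the variant call.
process_scan <- function(mesh, config) {
  if (config$orient) {
    mesh <- orient_scan(mesh, seed = config$orient_seed,
                        inlier_tol = config$inlier_tol,
                        method = config$facing,
                        manual_angle = config$manual_angle)$mesh
  }
  band <- crop_transverse(mesh, config$crop)
  comps <- find_leg_components(band, min_faces = config$min_faces)
  variant <- classify_visibility(comps, config$crop, delta = config$midline_delta)
  halves <- if (variant == "limited") {
    split_sagittal(comps[[1]], config$crop$sagittal_x)
  } else {
    two <- comps[1:2]
    mx <- vapply(two, function(m) mean(m$vertices[, 1]), 0)
    list(left = two[[which.max(mx)]], right = two[[which.min(mx)]])
  }
  segs <- lapply(c(left = "left", right = "right"), function(sd)
    leg_segment(repair_segment(halves[[sd]], config$crop, config$repair),
                side = sd, variant = variant, crop = config$crop))
  list(segments = segs, variant = variant)
}

#' Process one subject (two repeated scans)
#'
#' Runs the full workflow on both scans with the identical configuration:
#' orientation to the canonical frame, transverse cropping, component
#' extraction, visibility classification (which must agree between the two
#' scans), sagittal splitting for fused legs, surface repair, volumetry, and
#' pairing.
#'
#' @param scan1,scan2 `legvol_mesh` whole-body scans.
#' @param subject_id Subject identifier.
#' @param config A [pipeline_config()].
#' @return List of class `legvol_subject_result` with `measurements` (4-row
#'   tibble), `pairs` (2-row tibble from [pair_measurements()]) and `variant`.
#' @export
process_subject <- function(scan1, scan2, subject_id,
                            config = pipeline_config()) {
  r1 <- process_scan(scan1, config)
  r2 <- process_scan(scan2, config)
  if (r1$variant != r2$variant) {
    legvol_abort(sprintf(
      "visibility classification disagrees between scans of %s (%s vs %s)",
      subject_id, r1$variant, r2$variant), "legvol_pairing_error")
  }
  meas <- dplyr::bind_rows(c(
    lapply(r1$segments, measure_leg, subject_id = subject_id, scan_index = 1L),
    lapply(r2$segments, measure_leg, subject_id = subject_id, scan_index = 2L)))
  structure(list(measurements = meas, pairs = pair_measurements(meas),
                 variant = r1$variant),
            class = "legvol_subject_result")
}

#' Run the pipeline over a cohort
#'
#' Processes every subject of a simulated study (or any compatible list of
#' scan pairs), continuing past per-subject failures, and assembles the
#' measurement, pairing, summary, demographic and variant-comparison tables.
#' Optionally writes all tables as CSV.
#'
#' @param study A `legvol_study` from [simulate_precision_study()] (or
#'   [read_study()]).
#' @param config A [pipeline_config()]; defaults to the study's crop.
#' @param output_dir Optional directory for CSV output (`measurements.csv`,
#'   `pairs.csv`, `summary.csv`, `demographics.csv`, `comparison.csv`,
#'   `failures.csv`).
#' @return List of class `legvol_cohort` with tibbles `subjects`,
#'   `measurements`, `pairs`, `summary`, `demographics`, `comparison`, and
#'   `failures` (subject_id + condition message for subjects that errored).
#' @export
run_cohort <- function(study, config = NULL, output_dir = NULL) {
  stopifnot(inherits(study, "legvol_study"))
  if (is.null(config)) config <- pipeline_config(crop = study$crop)
  res <- vector("list", nrow(study$subjects))
  fails <- list()
  for (i in seq_len(nrow(study$subjects))) {
    sid <- study$subjects$subject_id[i]
    out <- tryCatch(
      process_subject(study$scans[[i]][[1]], study$scans[[i]][[2]], sid, config),
      legvol_error = function(e) e)
    if (inherits(out, "condition")) {
      fails[[length(fails) + 1L]] <- tibble::tibble(
        subject_id = sid, error_class = class(out)[1],
        message = conditionMessage(out))
    } else {
      res[[i]] <- out
    }
  }
  done <- !vapply(res, is.null, TRUE)
  if (!any(done)) legvol_abort("every subject failed", "legvol_empty_result")
  measurements <- dplyr::bind_rows(lapply(res[done], `[[`, "measurements"))
  pairs <- dplyr::bind_rows(lapply(res[done], `[[`, "pairs"))
  out <- structure(list(
    subjects = study$subjects,
    measurements = measurements,
    pairs = pairs,
    summary = cohort_summary(study$subjects, pairs),
    demographics = demographic_summary(study$subjects),
    comparison = compare_variants(pairs),
    failures = if (length(fails)) dplyr::bind_rows(fails) else
      tibble::tibble(subject_id = character(), error_class = character(),
                     message = character())),
    class = "legvol_cohort")
  if (!is.null(output_dir)) write_cohort(out, output_dir)
  out
}

write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- c("measurements", "pairs", "summary", "demographics", "comparison",
            "failures")
  for (t in tabs) {
    readr::write_csv(cohort[[t]], file.path(dir, paste0(t, ".csv")))
  }
  readr::write_csv(cohort$subjects, file.path(dir, "subjects.csv"))
  invisible(dir)
}

#' @export
print.legvol_cohort <- function(x, ...) {
  cat(sprintf("<legvol_cohort: %d subjects processed, %d failed>\n",
              dplyr::n_distinct(x$pairs$subject_id), nrow(x$failures)))
  print(x$summary)
  invisible(x)
}

# ---- study directory round-trip ---------------------------------------------

#' Write or read a simulated study as a scan directory
#'
#' Scans are stored as binary PLY (`<subject>_scan<k>.ply`) with `subjects.csv`,
#' `truth.csv` and `crop.csv` alongside, so a study can be processed by the
#' command-line interface or re-read later.
#'
#' @param study A `legvol_study`.
#' @param dir Directory path.
#' @return `write_study()` returns `dir` invisibly; `read_study()` a
#'   `legvol_study` (scans loaded eagerly).
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "legvol_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_len(nrow(study$subjects))) {
    sid <- study$subjects$subject_id[i]
    for (k in 1:2) {
      write_mesh(study$scans[[i]][[k]],
                 file.path(dir, sprintf("%s_scan%d.ply", sid, k)),
                 format = "ply_binary")
    }
  }
  readr::write_csv(study$subjects, file.path(dir, "subjects.csv"))
  readr::write_csv(study$truth, file.path(dir, "truth.csv"))
  readr::write_csv(tibble::tibble(z_low = study$crop$z_low,
                                  z_high = study$crop$z_high,
                                  sagittal_x = study$crop$sagittal_x),
                   file.path(dir, "crop.csv"))
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  subs_path <- file.path(dir, "subjects.csv")
  if (!file.exists(subs_path)) {
    legvol_abort(paste0("not a study directory (no subjects.csv): ", dir),
                 "legvol_io_error")
  }
  subjects <- readr::read_csv(subs_path, show_col_types = FALSE)
  crop_df <- readr::read_csv(file.path(dir, "crop.csv"), show_col_types = FALSE)
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) {
    readr::read_csv(truth_path, show_col_types = FALSE)
  } else NULL
  scans <- lapply(subjects$subject_id, function(sid) {
    lapply(1:2, function(k)
      read_mesh(file.path(dir, sprintf("%s_scan%d.ply", sid, k))))
  })
  structure(list(subjects = subjects, scans = scans, truth = truth,
                 crop = crop_config(crop_df$z_low, crop_df$z_high,
                                    crop_df$sagittal_x),
                 noise = NULL, seed = NA),
            class = "legvol_study")
}
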