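#' Write / read a study container
#'
#' A study is stored as a directory of plain-text files: `study.json`
#' (grid, frame schedules, ground truth if present, seed), `hed.csv` and
#' `acetate.csv` (one row per frame, one column per cell, headers
#' `r{ring}a{angle}`), and `blood_hed.csv` (`mid_time_min,activity`).
#' `read_study()` reconstructs the study; a written-and-reloaded study
#' quantifies identically.
#'
#' @param study A `synthetic_study` (or compatible list).
#' @param dir Output directory (created if missing).
#' @return `write_study()` returns `dir` invisibly; `read_study()` returns
#'   a `synthetic_study`-shaped list.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- study$grid
  meta <- list(
    grid = list(n_rings = grid$n_rings, n_angles = grid$n_angles),
    hed_durations_s = study$hed$schedule$duration_s,
    acetate_durations_s = study$acetate$schedule$duration_s,
    seed = study$seed
  )
  if (!is.null(study$truth)) {
    meta$truth <- unclass(study$truth)
  }
  jsonlite::write_json(meta, file.path(dir, "study.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_dpm_csv(study$hed, file.path(dir, "hed.csv"))
  write_dpm_csv(study$acetate, file.path(dir, "acetate.csv"))
  utils::write.csv(
    data.frame(mid_time_min = study$blood_hed$mid_time_min,
               activity = study$blood_hed$activity),
    file.path(dir, "blood_hed.csv"), row.names = FALSE
  )
  invisible(dir)
}

write_dpm_csv <- function(dpm, path) {
  ra <- cell_ring_angle(dpm$grid, seq_len(dpm$grid$n_cells))
  df <- as.data.frame(dpm$values)
  names(df) <- sprintf("r%da%d", ra$ring, ra$angle)
  utils::write.csv(df, path, row.names = FALSE)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "study.json"), simplifyVector = TRUE)
  grid <- polar_grid(meta$grid$n_rings, meta$grid$n_angles)
  hed_sched <- frame_schedule(meta$hed_durations_s)
  ace_sched <- frame_schedule(meta$acetate_durations_s)
  hed_vals <- as.matrix(utils::read.csv(file.path(dir, "hed.csv")))
  ace_vals <- as.matrix(utils::read.csv(file.path(dir, "acetate.csv")))
  bc <- utils::read.csv(file.path(dir, "blood_hed.csv"))
  truth <- if (!is.null(meta$truth)) {
    study_truth(
      retention_true = meta$truth$retention_true,
      perfusion_defect_extent = meta$truth$perfusion_defect_extent,
      hed_defect_extent = meta$truth$hed_defect_extent,
      defect_depth = meta$truth$defect_depth,
      noise_scale = meta$truth$noise_scale,
      blood_params = as.list(meta$truth$blood_params)
    )
  }
  structure(
    list(
      hed = dynamic_polar_map(grid, hed_sched, hed_vals),
      acetate = dynamic_polar_map(grid, ace_sched, ace_vals),
      blood_hed = blood_curve(bc$mid_time_min, bc$activity),
      truth = truth,
      grid = grid,
      seed = if (!is.null(meta$seed)) as.integer(meta$seed) else NA_integer_
    ),
    class = "synthetic_study"
  )
}

#' Write / read a cohort table
#'
#' Plain CSV with the cohort columns; missing values are not permitted.
#'
#' @param cohort Cohort `data.frame` from [generate_cohort()].
#' @param path CSV path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` the
#'   validated `data.frame`.
#' @export
write_cohort <- function(cohort, path) {
  if (anyNA(cohort)) stop("cohort must not contain missing values")
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "age", "sex", "bnp", "lvef", "retention",
            "perfusion_defect", "hed_defect", "mismatch",
            "followup_months", "death_any", "death_cardiac",
            "composite_event", "composite_time_months")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop("cohort file lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyNA(cohort)) stop("cohort must not contain missing values")
  if (any(cohort$followup_months <= 0)) stop("followup_months must be > 0")
  if (any(cohort$death_cardiac > cohort$death_any)) {
    stop("death_cardiac = 1 requires death_any = 1")
  }
  if (any(cohort$composite_time_months > cohort$followup_months + 1e-9)) {
    stop("composite_time_months must not exceed followup_months")
  }
  cohort
}

#' Write a quantification result
#'
#' Writes a `quant_result` both as a one-row CSV and as JSON (reference
#' cell sets included in the JSON only).
#'
#' @param qr A `quant_result`.
#' @param stem Output path without extension; writes `<stem>.csv` and
#'   `<stem>.json`.
#' @return `stem`, invisibly.
#' @export
write_quant_result <- function(qr, stem) {
  df <- data.frame(
    retention = qr$retention,
    perfusion_defect = qr$perfusion_defect,
    hed_defect = qr$hed_defect,
    mismatch = qr$mismatch
  )
  utils::write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(
      retention = qr$retention,
      perfusion_defect = qr$perfusion_defect,
      hed_defect = qr$hed_defect,
      mismatch = qr$mismatch,
      reference_cells_hed = qr$reference_cells_hed,
      reference_cells_acetate = qr$reference_cells_acetate
    ),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(stem)
}
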