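# Cells in wedge fill order: whole angular columns first (angle 1, 2, ...,
# each apex-to-base), then a partial column filled ring by ring. The first
# n cells of this order form a contiguous region for every n, and the
# perfusion wedge (fewer cells) is automatically nested inside the HED
# wedge (more cells).
wedge_fill_order <- function(grid) {
  as.vector(vapply(
    seq_len(grid$n_angles),
    function(a) cell_index(grid, seq_len(grid$n_rings), rep(a, grid$n_rings)),
    integer(grid$n_rings)
  ))
}

# Number of cells realising `extent_pct` %LV. The extent must be exactly
# achievable on the grid (a whole number of cells); use snap_extent() to
# round an arbitrary extent first.
extent_to_cells <- function(grid, extent_pct) {
  n <- round(extent_pct / 100 * grid$n_cells)
  achieved <- 100 * n / grid$n_cells
  if (abs(achieved - extent_pct) > 1e-6) {
    stop(sprintf(
      paste0("extent %.4g %%LV is not representable on a %d x %d grid; ",
             "achievable extents are multiples of %.4g %%LV"),
      extent_pct, grid$n_rings, grid$n_angles, 100 * grid$cell_weight
    ))
  }
  as.integer(n)
}

#' Snap a defect extent to the grid's achievable values
#'
#' Defect extents are realised as whole cells, so only multiples of one
#' cell weight (in %LV) are representable. This rounds an arbitrary extent
#' to the nearest achievable value.
#'
#' @param grid A `polar_grid`.
#' @param extent_pct Requested extent, %LV.
#' @return The nearest achievable extent, %LV.
#' @export
snap_extent <- function(grid, extent_pct) {
  100 * round(extent_pct / 100 * grid$n_cells) / grid$n_cells
}

#' Generate a synthetic dynamic PET study with known ground truth
#'
#' Builds paired HED and acetate dynamic polar-map acquisitions plus an
#' arterial blood curve such that the quantification stage provably
#' recovers the ground truth:
#'
#' * Defects are contiguous angular wedges (the perfusion wedge nested
#'   inside the HED wedge) whose cell totals equal the requested extents
#'   exactly; extents must be achievable as whole cells on the grid
#'   (an error lists the granularity otherwise; use [snap_extent()] to
#'   round first). Inside a defect, uptake is `defect_depth x normal`.
#' * The noise-free late (30--40 min) HED uptake of non-defect cells
#'   equals `(retention_true / 100) x integral of the generated blood
#'   curve`, so the retention index reproduces `retention_true` exactly in
#'   the noise-free case.
#' * Acetate frames 11 onward hold the perfusion pattern, so the summed
#'   frames 11--13 image shows the perfusion defect only.
#'
#' Earlier frames follow simple monotone time-activity shapes (a linear
#' wash-in for HED, a 100-s ramp for acetate); only the frames the
#' quantification stage reads are calibrated. Per-cell, per-frame Gaussian
#' noise with SD `noise_scale * sqrt(activity / duration_s)` emulates
#' Poisson-like count statistics; values are truncated at zero.
#' Regeneration with the same truth, grid and seed is bit-for-bit
#' identical.
#'
#' @param truth A `study_truth`.
#' @param grid A `polar_grid`.
#' @param seed Integer seed.
#' @return An object of class `synthetic_study` with fields `hed`,
#'   `acetate` (dynamic polar maps), `blood_hed` (`blood_curve`), `truth`,
#'   `grid`, `seed`.
#' @examples
#' st <- generate_study(study_truth(retention_true = 9), polar_grid(), seed = 7)
#' quantify_study(st)
#' @export
generate_study <- function(truth, grid = polar_grid(), seed = 1L) {
  stopifnot(inherits(truth, "study_truth"), inherits(grid, "polar_grid"))
  n_perf <- extent_to_cells(grid, truth$perfusion_defect_extent)
  n_hed <- extent_to_cells(grid, truth$hed_defect_extent)

  order_cells <- wedge_fill_order(grid)
  perf_cells <- order_cells[seq_len(n_perf)]
  hed_cells <- order_cells[seq_len(n_hed)]

  hed_sched <- hed_schedule()
  ace_sched <- acetate_schedule()

  blood <- generate_blood_curve(truth, hed_sched, seed = derive_seed(seed, 1L))
  blood_int <- integrate_blood_curve(blood, hed_sched$total_s / 60)

  # Late HED uptake per cell (kBq/mL): calibrated against the actual
  # (possibly noisy) blood curve so the retention numerator/denominator
  # pair stays consistent.
  uptake_late <- rep(truth$retention_true / 100 * blood_int, grid$n_cells)
  uptake_late[hed_cells] <- uptake_late[hed_cells] * truth$defect_depth

  # HED dynamics: linear wash-in reaching the late value exactly at the
  # final frame's mid-time.
  hed_mid <- frame_mid_min(hed_sched)
  hed_shape <- hed_mid / hed_mid[length(hed_mid)]
  hed_clean <- outer(hed_shape, uptake_late)

  # Acetate dynamics: perfusion pattern scaled by a 100-s injection ramp;
  # frames 11+ (mid-times >= 130 s) carry the pattern unscaled.
  perf_norm <- 10  # nominal myocardial perfusion activity, kBq/mL
  perf_vals <- rep(perf_norm, grid$n_cells)
  perf_vals[perf_cells] <- perf_norm * truth$defect_depth
  ace_shape <- pmin(1, ace_sched$mid_s / 100)
  ace_clean <- outer(ace_shape, perf_vals)

  if (truth$noise_scale > 0) {
    hed_clean <- with_local_seed(derive_seed(seed, 2L), {
      sd <- truth$noise_scale * sqrt(hed_clean / hed_sched$duration_s)
      pmax(hed_clean + stats::rnorm(length(hed_clean), sd = sd), 0)
    })
    ace_clean <- with_local_seed(derive_seed(seed, 3L), {
      sd <- truth$noise_scale * sqrt(ace_clean / ace_sched$duration_s)
      pmax(ace_clean + stats::rnorm(length(ace_clean), sd = sd), 0)
    })
  }

  structure(
    list(
      hed = dynamic_polar_map(grid, hed_sched, hed_clean),
      acetate = dynamic_polar_map(grid, ace_sched, ace_clean),
      blood_hed = blood,
      truth = truth,
      grid = grid,
      seed = as.integer(seed)
    ),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study (seed ", x$seed, ")\n", sep = "")
  print(x$truth)
  print(x$grid)
  invisible(x)
}
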