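#' Static polar map
#'
#' One value per grid cell: activity in kBq/mL, or a dimensionless fraction
#' of the reference-region mean after normalization.
#'
#' @param grid A `polar_grid`.
#' @param values Numeric vector of length `grid$n_cells`, finite.
#' @param normalized Logical flag; `TRUE` after [normalize_polar_map()].
#' @return An object of class `polar_map`.
#' @export
polar_map <- function(grid, values, normalized = FALSE) {
  stopifnot(inherits(grid, "polar_grid"))
  values <- as.numeric(values)
  if (length(values) != grid$n_cells) {
    stop(sprintf("expected %d cell values, got %d", grid$n_cells, length(values)))
  }
  if (any(!is.finite(values))) stop("polar map values must be finite")
  structure(
    list(grid = grid, values = values, normalized = isTRUE(normalized)),
    class = "polar_map"
  )
}

#' @export
print.polar_map <- function(x, ...) {
  cat(sprintf(
    "polar_map: %d cells%s, range [%.3g, %.3g]\n",
    x$grid$n_cells, if (x$normalized) " (normalized)" else "",
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Dynamic polar map
#'
#' Per-frame activity on the polar grid: a frames x cells matrix tied to a
#' frame schedule. All values are assumed decay-corrected kBq/mL.
#'
#' @param grid A `polar_grid`.
#' @param schedule A `frame_schedule`.
#' @param values Numeric matrix, `n_frames(schedule)` rows and
#'   `grid$n_cells` columns, non-negative.
#' @return An object of class `dynamic_polar_map`.
#' @export
dynamic_polar_map <- function(grid, schedule, values) {
  stopifnot(inherits(grid, "polar_grid"), inherits(schedule, "frame_schedule"))
  values <- as.matrix(values)
  if (nrow(values) != n_frames(schedule)) {
    stop("frame count of values does not match the schedule")
  }
  if (ncol(values) != grid$n_cells) {
    stop("cell count of values does not match the grid")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("dynamic polar map values must be finite and >= 0")
  }
  dimnames(values) <- NULL
  structure(
    list(grid = grid, schedule = schedule, values = values),
    class = "dynamic_polar_map"
  )
}

#' @export
print.dynamic_polar_map <- function(x, ...) {
  cat(sprintf(
    "dynamic_polar_map: %d frames x %d cells, %.0f s acquisition\n",
    n_frames(x$schedule), x$grid$n_cells, x$schedule$total_s
  ))
  invisible(x)
}

#' Sum (time-average) a window of frames into a static polar map
#'
#' Computes the cellwise duration-weighted mean of frames `first..last`,
#' i.e. the time-averaged activity over the window. Units stay in kBq/mL
#' and the result is invariant to re-binning of frames within the window.
#' With `first == last` the frame is returned unchanged.
#'
#' @param dpm A `dynamic_polar_map`.
#' @param first,last 1-based frame indices, `1 <= first <= last <= n`.
#' @return A `polar_map` (not normalized).
#' @export
sum_frames <- function(dpm, first, last) {
  stopifnot(inherits(dpm, "dynamic_polar_map"))
  nf <- n_frames(dpm$schedule)
  first <- as.integer(first)
  last <- as.integer(last)
  if (is.na(first) || is.na(last) || first < 1L || last > nf || first > last) {
    stop(sprintf("frame window [%s, %s] out of range 1..%d", first, last, nf))
  }
  idx <- first:last
  w <- dpm$schedule$duration_s[idx]
  vals <- colSums(dpm$values[idx, , drop = FALSE] * w) / sum(w)
  polar_map(dpm$grid, vals, normalized = FALSE)
}
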