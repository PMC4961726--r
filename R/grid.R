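#' Polar (bull's-eye) sampling grid of the left ventricle
#'
#' The LV myocardium is projected onto `n_rings` concentric rings
#' (apex to base) times `n_angles` angular sectors. Every cell carries an
#' equal weight `1 / (n_rings * n_angles)` of the LV, so %LV arithmetic is
#' exact: a set of cells covers `100 * length(set) * cell_weight` %LV.
#'
#' Cells are indexed 1..n_cells with `cell = (ring - 1) * n_angles + angle`.
#' Adjacency is the 4-neighbourhood: same ring with +/-1 angular step
#' (wrapping around), and same angle with +/-1 ring. There is no special
#' adjacency across the apex pole.
#'
#' @param n_rings Number of rings (apex to base), >= 1.
#' @param n_angles Number of angular sectors, >= 3.
#' @return An object of class `polar_grid`.
#' @examples
#' g <- polar_grid()          # default 10 x 40 = 400 cells, 0.25 %LV each
#' g$cell_weight * g$n_cells  # 1
#' @export
polar_grid <- function(n_rings = 10L, n_angles = 40L) {
  n_rings <- as.integer(n_rings)
  n_angles <- as.integer(n_angles)
  if (is.na(n_rings) || n_rings < 1L) stop("n_rings must be >= 1")
  if (is.na(n_angles) || n_angles < 3L) stop("n_angles must be >= 3")
  n_cells <- n_rings * n_angles
  structure(
    list(
      n_rings = n_rings,
      n_angles = n_angles,
      n_cells = n_cells,
      cell_weight = 1 / n_cells
    ),
    class = "polar_grid"
  )
}

#' @export
print.polar_grid <- function(x, ...) {
  cat(sprintf(
    "polar_grid: %d rings x %d angles = %d cells (%.4g %%LV each)\n",
    x$n_rings, x$n_angles, x$n_cells, 100 * x$cell_weight
  ))
  invisible(x)
}

#' Linear cell index from (ring, angle)
#' @param grid A `polar_grid`.
#' @param ring Ring index, 1..n_rings (1 = apex).
#' @param angle Angular sector index, 1..n_angles.
#' @return Integer cell index in 1..n_cells.
#' @export
cell_index <- function(grid, ring, angle) {
  stopifnot(all(ring >= 1L & ring <= grid$n_rings),
            all(angle >= 1L & angle <= grid$n_angles))
  (as.integer(ring) - 1L) * grid$n_angles + as.integer(angle)
}

#' Ring and angle of a linear cell index
#' @param grid A `polar_grid`.
#' @param cell Cell index in 1..n_cells.
#' @return A list with integer vectors `ring` and `angle`.
#' @export
cell_ring_angle <- function(grid, cell) {
  cell <- as.integer(cell)
  stopifnot(all(cell >= 1L & cell <= grid$n_cells))
  list(
    ring = (cell - 1L) %/% grid$n_angles + 1L,
    angle = (cell - 1L) %% grid$n_angles + 1L
  )
}

# Adjacency list of the grid graph: for each cell, its 4-neighbours
# (angular wraparound, no pole adjacency). Rings with n_angles <= 2 are
# excluded by the constructor, so the two angular neighbours are distinct.
grid_neighbors <- function(grid) {
  nr <- grid$n_rings
  na <- grid$n_angles
  lapply(seq_len(grid$n_cells), function(cell) {
    ring <- (cell - 1L) %/% na + 1L
    angle <- (cell - 1L) %% na + 1L
    nb <- c(
      (ring - 1L) * na + (angle %% na) + 1L,          # angle + 1 (wrap)
      (ring - 1L) * na + ((angle - 2L) %% na) + 1L    # angle - 1 (wrap)
    )
    if (ring > 1L) nb <- c(nb, (ring - 2L) * na + angle)
    if (ring < nr) nb <- c(nb, ring * na + angle)
    sort(nb)
  })
}

# TRUE if the cell set is connected under grid adjacency.
cells_connected <- function(grid, cells, neighbors = grid_neighbors(grid)) {
  cells <- as.integer(cells)
  if (length(cells) <= 1L) return(TRUE)
  in_set <- logical(grid$n_cells)
  in_set[cells] <- TRUE
  seen <- logical(grid$n_cells)
  queue <- cells[1L]
  seen[queue] <- TRUE
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    nb <- neighbors[[v]]
    nb <- nb[in_set[nb] & !seen[nb]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  sum(seen) == length(cells)
}
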