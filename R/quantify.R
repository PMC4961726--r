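#' Find the reference region: the k connected cells with highest mean uptake
#'
#' Polar maps are normalized to the mean of a small connected patch of
#' sectors with the highest overall uptake (default k = 6). Connectivity is
#' the grid 4-neighbourhood (angular wraparound, no pole adjacency).
#'
#' Two search strategies are provided. `"greedy"` grows regions from the
#' brightest seed cells with a beam: every kept partial region is extended
#' by every adjacent cell, duplicates are merged, and the highest-sum
#' regions (beam width `max(n_seeds, 64)`) survive to the next size; the
#' final best region is polished with connectivity-preserving one- and
#' two-cell swaps. `"exhaustive"` enumerates every connected k-subset and is
#' exact; it is intended for small grids (it refuses grids above
#' `exhaustive_limit` cells) and serves as the oracle for the greedy
#' search. Ties in mean are broken toward the lexicographically smallest
#' sorted cell-index set, so both methods are deterministic.
#'
#' @param pm A `polar_map`, not yet normalized.
#' @param k Region size in cells (default 6).
#' @param method `"greedy"` (default) or `"exhaustive"`.
#' @param n_seeds Number of seed cells for the greedy search.
#' @param exhaustive_limit Maximum cell count accepted by the exhaustive
#'   search.
#' @return Sorted integer vector of k cell indices, connected under grid
#'   adjacency.
#' @export
find_reference_region <- function(pm, k = 6L,
                                  method = c("greedy", "exhaustive"),
                                  n_seeds = 10L,
                                  exhaustive_limit = 64L) {
  stopifnot(inherits(pm, "polar_map"))
  method <- match.arg(method)
  k <- as.integer(k)
  if (pm$normalized) stop("reference search expects an unnormalized map")
  if (k < 1L) stop("k must be >= 1")
  if (k > pm$grid$n_cells) {
    stop(sprintf("k = %d exceeds the %d-cell grid", k, pm$grid$n_cells))
  }
  nb <- grid_neighbors(pm$grid)
  if (method == "exhaustive") {
    if (pm$grid$n_cells > exhaustive_limit) {
      stop(sprintf(
        "exhaustive search limited to grids of <= %d cells (got %d)",
        exhaustive_limit, pm$grid$n_cells
      ))
    }
    ref_search_exhaustive(pm$values, nb, k)
  } else {
    ref_search_greedy(pm$values, nb, k, n_seeds)
  }
}

# TRUE if set `a` (sorted) is preferred over `b`: larger sum, ties broken
# toward the lexicographically smaller index vector.
better_set <- function(sum_a, a, sum_b, b) {
  if (is.null(b)) return(TRUE)
  if (sum_a != sum_b) return(sum_a > sum_b)
  cmp <- a - b
  nz <- which(cmp != 0)
  if (length(nz) == 0L) return(FALSE)
  cmp[nz[1L]] < 0
}

# Beam-guided region growing: start one partial region per seed cell,
# extend every region by every adjacent cell, deduplicate, keep the
# `beam` highest-sum regions, repeat until size k. The final best region
# is polished with connectivity-preserving swaps. Ties in the final sum
# are broken toward the lexicographically smallest index set.
ref_search_greedy <- function(values, nb, k, n_seeds) {
  n <- length(values)
  beam <- max(n_seeds, 64L)
  states <- as.list(order(-values, seq_len(n))[seq_len(min(beam, n))])
  for (size in seq_len(k - 1L)) {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    children <- vector("list", length(states) * 8L)
    n_child <- 0L
    for (st in states) {
      cand <- setdiff(unique(unlist(nb[st], use.names = FALSE)), st)
      for (v in cand) {
        ch <- sort(c(st, v))
        key <- paste(ch, collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          n_child <- n_child + 1L
          children[[n_child]] <- ch
        }
      }
    }
    children <- children[seq_len(n_child)]
    sums <- vapply(children, function(x) sum(values[x]), numeric(1))
    states <- children[order(-sums)[seq_len(min(beam, n_child))]]
  }
  best <- NULL
  best_sum <- -Inf
  for (st in states) {
    s_sum <- sum(values[st])
    if (better_set(s_sum, st, best_sum, best)) {
      best <- st
      best_sum <- s_sum
    }
  }
  refine_by_swaps(best, values, nb, n)
}

# Hill-climb on swaps: exchange one (then, at a stall, two) member cells
# for outside cells while keeping the set connected, whenever the total
# strictly increases. Terminates because the total strictly increases.
refine_by_swaps <- function(set, values, nb, n) {
  repeat {
    swap <- best_swap1(set, values, nb, n)
    if (!is.null(swap)) {
      set <- sort(c(setdiff(set, swap$out), swap$new))
      next
    }
    swap <- best_swap2(set, values, nb, n)
    if (is.null(swap)) return(sort(set))
    set <- sort(c(setdiff(set, swap$out), swap$new))
  }
}

# Best single-cell exchange improving the total, or NULL.
best_swap1 <- function(set, values, nb, n) {
  in_set <- logical(n)
  in_set[set] <- TRUE
  best_gain <- 1e-12
  best <- NULL
  for (u in set) {
    rest <- set[set != u]
    if (length(rest) > 1L && !connected_idx(rest, nb)) next
    cand <- unique(unlist(nb[rest], use.names = FALSE))
    cand <- cand[!in_set[cand]]
    if (length(cand) == 0L) next
    v <- cand[order(-values[cand], cand)][1L]
    gain <- values[v] - values[u]
    if (gain > best_gain) {
      best_gain <- gain
      best <- list(out = u, new = v)
    }
  }
  best
}

# Best two-cell exchange improving the total, or NULL. The two incoming
# cells may rely on each other for connectivity (v first, then w adjacent
# to rest + v).
best_swap2 <- function(set, values, nb, n) {
  k <- length(set)
  if (k < 3L) return(NULL)
  in_set <- logical(n)
  in_set[set] <- TRUE
  best_gain <- 1e-12
  best <- NULL
  pairs <- utils::combn(set, 2L)
  for (j in seq_len(ncol(pairs))) {
    out <- pairs[, j]
    rest <- setdiff(set, out)
    if (length(rest) > 1L && !connected_idx(rest, nb)) next
    cand_v <- unique(unlist(nb[rest], use.names = FALSE))
    cand_v <- cand_v[!in_set[cand_v]]
    loss <- sum(values[out])
    for (v in cand_v) {
      cand_w <- unique(c(unlist(nb[rest], use.names = FALSE), nb[[v]]))
      cand_w <- cand_w[!in_set[cand_w] & cand_w != v]
      if (length(cand_w) == 0L) next
      w <- cand_w[order(-values[cand_w], cand_w)][1L]
      gain <- values[v] + values[w] - loss
      if (gain > best_gain) {
        best_gain <- gain
        best <- list(out = out, new = c(v, w))
      }
    }
  }
  best
}

connected_idx <- function(cells, nb) {
  if (length(cells) <= 1L) return(TRUE)
  in_set <- integer(0)
  member <- cells
  seen <- member[1L]
  queue <- member[1L]
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    new <- intersect(nb[[v]], member)
    new <- setdiff(new, seen)
    seen <- c(seen, new)
    queue <- c(queue, new)
  }
  length(seen) == length(member)
}

# Exact enumeration of all connected k-subsets (each exactly once): for
# each root v in increasing order, extend subsets of {v, v+1, ...} that
# contain v, maintaining an extension frontier and a forbidden set so no
# subset is produced twice.
ref_search_exhaustive <- function(values, nb, k) {
  n <- length(values)
  best <- NULL
  best_sum <- -Inf
  consider <- function(set) {
    s <- sum(values[set])
    if (better_set(s, set, best_sum, best)) {
      best <<- set
      best_sum <<- s
    }
  }
  recurse <- function(set, frontier, forbidden) {
    if (length(set) == k) {
      consider(sort(set))
      return(invisible(NULL))
    }
    while (length(frontier)) {
      v <- frontier[[1L]]
      frontier <- frontier[-1L]
      new_nb <- setdiff(nb[[v]], c(set, frontier, forbidden, v))
      recurse(c(set, v), c(frontier, new_nb), forbidden)
      forbidden <- c(forbidden, v)
    }
  }
  for (root in seq_len(n - k + 1L)) {
    lower <- seq_len(root)  # roots are processed in increasing order
    recurse(root, setdiff(nb[[root]], lower), lower)
  }
  best
}

#' Normalize a polar map to a reference region
#'
#' Divides every cell by the mean of the reference cells; after the call
#' the reference mean is exactly 1.0 and the map is flagged normalized.
#'
#' @param pm A `polar_map`.
#' @param ref Integer vector of reference cell indices with positive mean.
#' @return A normalized `polar_map`.
#' @export
normalize_polar_map <- function(pm, ref) {
  stopifnot(inherits(pm, "polar_map"))
  ref <- as.integer(ref)
  if (length(ref) == 0L || any(ref < 1L | ref > pm$grid$n_cells)) {
    stop("ref must be a nonempty set of valid cell indices")
  }
  m <- mean(pm$values[ref])
  if (!is.finite(m) || m <= 0) stop("reference mean must be positive")
  polar_map(pm$grid, pm$values / m, normalized = TRUE)
}

#' Defect size of a normalized polar map
#'
#' Total cell weight of cells with normalized uptake strictly below the
#' cutoff threshold, expressed as a percentage of the LV myocardium (%LV).
#' A cell sitting exactly at the threshold is not counted as defect.
#'
#' @param pm_norm A normalized `polar_map`.
#' @param threshold Cutoff as a fraction of the reference mean, in (0, 1);
#'   default 0.60.
#' @return Defect size in %LV.
#' @export
defect_size <- function(pm_norm, threshold = 0.60) {
  stopifnot(inherits(pm_norm, "polar_map"))
  if (!pm_norm$normalized) stop("defect_size expects a normalized map")
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly inside (0, 1)")
  }
  100 * sum(pm_norm$values < threshold) * pm_norm$grid$cell_weight
}

#' Mismatch size
#'
#' Innervation/perfusion mismatch: HED defect size minus perfusion defect
#' size, the extent of myocardium that is denervated but perfused. The
#' literal difference is returned (it may be negative).
#'
#' @param hed_defect HED defect size, %LV in [0, 100].
#' @param perfusion_defect Perfusion defect size, %LV in [0, 100].
#' @return Mismatch size, %LV.
#' @examples
#' mismatch_size(68, 32)  # 36
#' @export
mismatch_size <- function(hed_defect, perfusion_defect) {
  stopifnot(
    is.numeric(hed_defect), is.numeric(perfusion_defect),
    hed_defect >= 0, hed_defect <= 100,
    perfusion_defect >= 0, perfusion_defect <= 100
  )
  hed_defect - perfusion_defect
}

#' Global HED retention index
#'
#' The LV-averaged late (final-frame) myocardial HED concentration divided
#' by the time-integral of the arterial blood activity curve from
#' injection to the end of the acquisition. With equal cell weights the
#' LV average is the plain mean over all cells. Reported by default as
#' %/min (the raw 1/min ratio multiplied by 100, matching the magnitudes
#' used clinically); set `retention_scale = "per_min"` for the raw ratio.
#'
#' @param hed A `dynamic_polar_map` of the HED acquisition; the final
#'   frame is taken as the late image.
#' @param blood A `blood_curve` covering the acquisition.
#' @param retention_scale `"percent_per_min"` (default) or `"per_min"`.
#' @return Retention index.
#' @export
retention_index <- function(hed, blood,
                            retention_scale = c("percent_per_min", "per_min")) {
  stopifnot(inherits(hed, "dynamic_polar_map"), inherits(blood, "blood_curve"))
  retention_scale <- match.arg(retention_scale)
  nf <- n_frames(hed$schedule)
  late <- sum_frames(hed, nf, nf)
  uptake <- sum(late$values) * hed$grid$cell_weight
  integral <- integrate_blood_curve(blood, hed$schedule$total_s / 60)
  if (integral <= 0) stop("blood integral must be positive; retention undefined")
  ratio <- uptake / integral
  if (retention_scale == "percent_per_min") 100 * ratio else ratio
}

#' Quantify a dynamic PET study
#'
#' Orchestrates the full measurement for one study, producing the four
#' imaging parameters: global HED retention, perfusion defect size, HED
#' defect size, and mismatch size. The perfusion defect is measured on the
#' normalized time-averaged acetate frames 11--13 (the relative perfusion
#' image); the HED defect on the normalized late (30--40 min) HED image;
#' each map is normalized against its own reference region.
#'
#' @param study A `synthetic_study` or a study loaded by [read_study()].
#' @param threshold Defect cutoff as a fraction of the reference mean.
#' @param k_ref Reference-region size in cells.
#' @param perfusion_frames Length-2 vector of 1-based acetate frame indices
#'   summed into the perfusion image.
#' @param retention_scale Passed to [retention_index()].
#' @param method Reference-search method, see [find_reference_region()].
#' @return An object of class `quant_result`: a list with `retention`,
#'   `perfusion_defect`, `hed_defect`, `mismatch` (%LV) and the reference
#'   cell sets `reference_cells_hed`, `reference_cells_acetate`.
#' @examples
#' st <- generate_study(
#'   study_truth(9, perfusion_defect_extent = 32, hed_defect_extent = 68),
#'   polar_grid(), seed = 1
#' )
#' quantify_study(st)
#' @export
quantify_study <- function(study, threshold = 0.60, k_ref = 6L,
                           perfusion_frames = c(11L, 13L),
                           retention_scale = c("percent_per_min", "per_min"),
                           method = c("greedy", "exhaustive")) {
  retention_scale <- match.arg(retention_scale)
  method <- match.arg(method)
  stopifnot(
    inherits(study$hed, "dynamic_polar_map"),
    inherits(study$acetate, "dynamic_polar_map"),
    inherits(study$blood_hed, "blood_curve")
  )
  perf_map <- sum_frames(study$acetate, perfusion_frames[1L], perfusion_frames[2L])
  hed_map <- sum_frames(study$hed, n_frames(study$hed$schedule),
                        n_frames(study$hed$schedule))
  ref_ace <- find_reference_region(perf_map, k = k_ref, method = method)
  ref_hed <- find_reference_region(hed_map, k = k_ref, method = method)
  perf_def <- defect_size(normalize_polar_map(perf_map, ref_ace), threshold)
  hed_def <- defect_size(normalize_polar_map(hed_map, ref_hed), threshold)
  structure(
    list(
      retention = retention_index(study$hed, study$blood_hed, retention_scale),
      perfusion_defect = perf_def,
      hed_defect = hed_def,
      mismatch = mismatch_size(hed_def, perf_def),
      reference_cells_hed = ref_hed,
      reference_cells_acetate = ref_ace
    ),
    class = "quant_result"
  )
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf(
    paste0("quant_result: retention %.3g, perfusion defect %.3g %%LV, ",
           "HED defect %.3g %%LV, mismatch %.3g %%LV\n"),
    x$retention, x$perfusion_defect, x$hed_defect, x$mismatch
  ))
  invisible(x)
}
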