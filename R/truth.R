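#' Ground-truth parameters of a synthetic study
#'
#' @param retention_true True global HED retention, %/min (the late-uptake /
#'   blood-integral ratio times 100).
#' @param perfusion_defect_extent Perfusion defect extent, %LV in [0, 100].
#' @param hed_defect_extent HED (innervation) defect extent, %LV; must be >=
#'   the perfusion extent (the mismatch phenotype: denervated but perfused
#'   tissue surrounds the perfusion defect).
#' @param defect_depth Uptake inside a defect as a fraction of normal uptake,
#'   in [0, 1). A depth below the 0.60 defect threshold makes the implanted
#'   defect detectable.
#' @param noise_scale Dimensionless noise multiplier; 0 = noise-free.
#' @param blood_params List with `amplitude` (kBq/mL), `alpha` (shape),
#'   `beta_min` (scale, minutes), `recirc` (recirculation fraction of peak).
#' @return An object of class `study_truth`.
#' @examples
#' study_truth(retention_true = 9)
#' @export
study_truth <- function(retention_true,
                        perfusion_defect_extent = 0,
                        hed_defect_extent = perfusion_defect_extent,
                        defect_depth = 0.4,
                        noise_scale = 0,
                        blood_params = list(amplitude = 20, alpha = 2,
                                            beta_min = 0.5, recirc = 0.15)) {
  stopifnot(is.numeric(retention_true), length(retention_true) == 1L,
            is.finite(retention_true), retention_true > 0)
  if (perfusion_defect_extent < 0 || perfusion_defect_extent > 100 ||
      hed_defect_extent < 0 || hed_defect_extent > 100) {
    stop("defect extents must lie in [0, 100] %LV")
  }
  if (hed_defect_extent < perfusion_defect_extent) {
    stop("hed_defect_extent must be >= perfusion_defect_extent")
  }
  if (defect_depth < 0 || defect_depth >= 1) {
    stop("defect_depth must lie in [0, 1)")
  }
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  need <- c("amplitude", "alpha", "beta_min", "recirc")
  if (!all(need %in% names(blood_params))) {
    stop("blood_params needs fields: ", paste(need, collapse = ", "))
  }
  bp <- lapply(blood_params[need], as.numeric)
  if (any(vapply(bp, function(v) !is.finite(v) || v < 0, logical(1)))) {
    stop("blood_params must be finite and >= 0")
  }
  if (bp$alpha <= 0 || bp$beta_min <= 0) {
    stop("blood_params alpha and beta_min must be > 0")
  }
  structure(
    list(
      retention_true = retention_true,
      perfusion_defect_extent = perfusion_defect_extent,
      hed_defect_extent = hed_defect_extent,
      defect_depth = defect_depth,
      noise_scale = noise_scale,
      blood_params = bp
    ),
    class = "study_truth"
  )
}

#' @export
print.study_truth <- function(x, ...) {
  cat(sprintf(
    "study_truth: retention %.3g %%/min, defects %.3g/%.3g %%LV (depth %.2f), noise %.2f\n",
    x$retention_true, x$perfusion_defect_extent, x$hed_defect_extent,
    x$defect_depth, x$noise_scale
  ))
  invisible(x)
}
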