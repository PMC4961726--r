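#' Arterial blood time-activity curve
#'
#' One activity sample per frame, taken at the frame mid-time. Activities
#' are decay-corrected kBq/mL; times are minutes post-injection.
#'
#' @param mid_time_min Strictly increasing sample times, minutes.
#' @param activity Non-negative activities, kBq/mL, same length.
#' @return An object of class `blood_curve`.
#' @export
blood_curve <- function(mid_time_min, activity) {
  mid_time_min <- as.numeric(mid_time_min)
  activity <- as.numeric(activity)
  if (length(mid_time_min) == 0L) stop("blood curve must have at least one sample")
  if (length(mid_time_min) != length(activity)) {
    stop("mid_time_min and activity must have the same length")
  }
  if (any(!is.finite(mid_time_min)) || any(diff(mid_time_min) <= 0) ||
      mid_time_min[1] <= 0) {
    stop("sample mid-times must be positive and strictly increasing")
  }
  if (any(!is.finite(activity)) || any(activity < 0)) {
    stop("activities must be finite and >= 0")
  }
  structure(
    list(mid_time_min = mid_time_min, activity = activity),
    class = "blood_curve"
  )
}

#' @export
print.blood_curve <- function(x, ...) {
  cat(sprintf(
    "blood_curve: %d samples over %.1f min, peak %.3g kBq/mL\n",
    length(x$activity), max(x$mid_time_min), max(x$activity)
  ))
  invisible(x)
}

# Noise-free blood model: gamma-variate bolus peaking at t = alpha * beta
# with peak value `amplitude`, plus a recirculation plateau rising to
# `recirc * amplitude` with a fixed 5-min wash-in constant.
blood_model <- function(t_min, amplitude, alpha, beta_min, recirc) {
  tp <- alpha * beta_min
  bolus <- amplitude * (t_min / tp)^alpha * exp(alpha - t_min / beta_min)
  tail <- recirc * amplitude * (1 - exp(-t_min / 5))
  bolus + tail
}

#' Generate a blood activity curve for a study
#'
#' Samples the generator's blood model (gamma-variate bolus plus a
#' recirculation plateau) at the frame mid-times of `schedule`. With
#' `truth$noise_scale > 0`, independent Gaussian noise with standard
#' deviation `noise_scale * 0.02 * amplitude` is added per sample and the
#' result truncated at zero; with `noise_scale = 0` the curve is
#' noise-free. Deterministic given `seed`.
#'
#' @param truth A `study_truth` (uses `blood_params` and `noise_scale`).
#' @param schedule A `frame_schedule`.
#' @param seed Integer seed for the sampling noise.
#' @return A `blood_curve` with one sample per frame.
#' @export
generate_blood_curve <- function(truth, schedule, seed = 1L) {
  stopifnot(inherits(truth, "study_truth"), inherits(schedule, "frame_schedule"))
  bp <- truth$blood_params
  t_min <- frame_mid_min(schedule)
  clean <- blood_model(t_min, bp$amplitude, bp$alpha, bp$beta_min, bp$recirc)
  act <- if (truth$noise_scale > 0) {
    with_local_seed(seed, {
      pmax(0, clean + stats::rnorm(length(clean),
                                   sd = truth$noise_scale * 0.02 * bp$amplitude))
    })
  } else {
    clean
  }
  blood_curve(t_min, act)
}

#' Integrate a blood activity curve
#'
#' Trapezoidal integral of the sampled curve from t = 0 (a zero-activity
#' point is prepended at t = 0) to `t_end_min`. If `t_end_min` falls
#' between samples the curve is interpolated linearly; beyond the last
#' sample it is extended as a constant, but only up to half the last
#' inter-sample spacing (further extrapolation errors).
#'
#' @param bc A `blood_curve`.
#' @param t_end_min Upper integration limit, minutes, > 0.
#' @return Integral in kBq.min/mL.
#' @export
integrate_blood_curve <- function(bc, t_end_min) {
  stopifnot(inherits(bc, "blood_curve"))
  t_end_min <- as.numeric(t_end_min)
  if (!is.finite(t_end_min) || t_end_min <= 0) stop("t_end_min must be > 0")
  t <- c(0, bc$mid_time_min)
  a <- c(0, bc$activity)
  n <- length(t)
  half_gap <- if (n >= 3) (t[n] - t[n - 1]) / 2 else t[n] / 2
  if (t_end_min > t[n] + half_gap + 1e-9) {
    stop(sprintf(
      "t_end_min = %.4g min is beyond the sampled curve (last mid-time %.4g min)",
      t_end_min, t[n]
    ))
  }
  if (t_end_min >= t[n]) {
    # constant extension past the last sample
    t <- c(t, t_end_min)
    a <- c(a, a[n])
  } else {
    keep <- t < t_end_min
    a_end <- stats::approx(t, a, xout = t_end_min)$y
    t <- c(t[keep], t_end_min)
    a <- c(a[keep], a_end)
  }
  sum(diff(t) * (utils::head(a, -1) + utils::tail(a, -1)) / 2)
}
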