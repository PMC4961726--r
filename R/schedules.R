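#' Dynamic acquisition frame schedule
#'
#' A `frame_schedule` is the timing backbone of a dynamic PET acquisition:
#' an ordered set of contiguous frames described by start time and duration
#' in seconds. Frame indexing is 1-based throughout the package.
#'
#' @param durations_s Numeric vector of frame durations in seconds, all
#'   strictly positive. Frames are contiguous and start at 0 s.
#' @return An object of class `frame_schedule` with fields `start_s`,
#'   `duration_s`, `mid_s` (frame mid-times, seconds) and `total_s`.
#' @examples
#' sched <- frame_schedule(c(30, 30, 60))
#' sched$total_s  # 120
#' @export
frame_schedule <- function(durations_s) {
  durations_s <- as.numeric(durations_s)
  if (length(durations_s) == 0L) {
    stop("a frame schedule needs at least one frame")
  }
  if (any(!is.finite(durations_s)) || any(durations_s <= 0)) {
    stop("frame durations must be finite and strictly positive")
  }
  start_s <- cumsum(c(0, durations_s[-length(durations_s)]))
  structure(
    list(
      start_s = start_s,
      duration_s = durations_s,
      mid_s = start_s + durations_s / 2,
      total_s = sum(durations_s)
    ),
    class = "frame_schedule"
  )
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf(
    "frame_schedule: %d frames, total %.0f s (%.1f min)\n",
    n_frames(x), x$total_s, x$total_s / 60
  ))
  invisible(x)
}

#' Number of frames in a schedule
#' @param schedule A `frame_schedule`.
#' @return Integer frame count.
#' @export
n_frames <- function(schedule) length(schedule$duration_s)

#' Frame mid-times in minutes
#' @param schedule A `frame_schedule`.
#' @return Numeric vector of frame mid-times, minutes post-injection.
#' @export
frame_mid_min <- function(schedule) schedule$mid_s / 60

#' Built-in acquisition protocols
#'
#' The two canned dynamic protocols used by this package. The
#' hydroxyephedrine (HED) acquisition runs 40 min in 14 frames
#' (6 x 30, 2 x 60, 2 x 150, 2 x 300, 2 x 600 s); its final frame is the
#' 30--40 min image used for the retention index. The acetate acquisition
#' has 21 frames (10 x 10, 1 x 60, 5 x 100, 3 x 80, 2 x 300 s); frames
#' 11--13 of it are summed into the relative perfusion image.
#'
#' @return A `frame_schedule`.
#' @examples
#' hed_schedule()$total_s      # 2400 s = 40 min
#' n_frames(acetate_schedule())  # 21
#' @export
hed_schedule <- function() {
  frame_schedule(c(rep(30, 6), rep(60, 2), rep(150, 2), rep(300, 2), rep(600, 2)))
}

#' @rdname hed_schedule
#' @export
acetate_schedule <- function() {
  frame_schedule(c(rep(10, 10), 60, rep(100, 5), rep(80, 3), rep(300, 2)))
}
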