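#' Frame schedule for dynamic PET
#'
#' A frame schedule holds the start time and duration (seconds) of each time
#' frame of a dynamic acquisition. Frames must be contiguous (each frame starts
#' where the previous one ends) and non-overlapping, with strictly positive
#' durations. Frame mid-times `mid = start + duration/2` are the time points at
#' which model curves are evaluated when computing fit residuals.
#'
#' @param start numeric vector of frame start times (s), first frame at 0.
#' @param duration numeric vector of frame durations (s), same length.
#' @return An object of class `frame_schedule` with fields `start`, `duration`,
#'   `mid` and `M` (frame count).
#' @examples
#' sch <- default_htr_schedule()
#' sch$M        # 90
#' sch$mid[1]   # 0.5 s
#' @export
frame_schedule <- function(start, duration) {
  if (length(start) != length(duration) || length(start) == 0L)
    stopf("start and duration must be non-empty vectors of equal length")
  if (!all(is.finite(start)) || !all(is.finite(duration)))
    stopf("frame times must be finite")
  if (any(duration <= 0)) stopf("frame durations must be > 0")
  if (is.unsorted(start, strictly = TRUE)) stopf("frame starts must be strictly increasing")
  ends <- start + duration
  if (length(start) > 1L) {
    gap <- start[-1L] - ends[-length(ends)]
    if (any(abs(gap) > 1e-9))
      stopf("frames must be contiguous and non-overlapping (gap/overlap of %.3g s found)",
            max(abs(gap)))
  }
  structure(list(start = as.numeric(start), duration = as.numeric(duration),
                 mid = as.numeric(start + duration / 2), M = length(start)),
            class = "frame_schedule")
}

#' Default 2-minute high-temporal-resolution schedule
#'
#' 60 frames of 1 s followed by 30 frames of 2 s (120 s total, 90 frames),
#' the sampling used for early dynamic scans in this package.
#' @return A `frame_schedule`.
#' @export
default_htr_schedule <- function() {
  dur <- c(rep(1, 60), rep(2, 30))
  frame_schedule(start = cumsum(c(0, dur[-length(dur)])), duration = dur)
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("Frame schedule: %d frames, %.6g s total (%.6g to %.6g s)\n",
              x$M, sum(x$duration), x$start[1], x$start[x$M] + x$duration[x$M]))
  invisible(x)
}

#' Total scan duration of a schedule (s)
#' @param schedule a `frame_schedule`.
#' @export
schedule_end <- function(schedule) {
  schedule$start[schedule$M] + schedule$duration[schedule$M]
}

#' Convert a flow-type rate between per-minute and per-second time bases
#'
#' Rates are reported in the conventional units ml/min/cm^3 (or min^-1) but all
#' internal time arithmetic is in seconds.
#'
#' @param value rate in ml/min/cm^3 (or min^-1).
#' @return `per_minute_to_per_second`: value/60. `per_second_to_per_minute`: value*60.
#' @export
per_minute_to_per_second <- function(value) {
  if (any(!is.finite(value)) || any(value < 0)) stopf("rate must be finite and >= 0")
  value / 60
}

#' @rdname per_minute_to_per_second
#' @export
per_second_to_per_minute <- function(value) {
  if (any(!is.finite(value)) || any(value < 0)) stopf("rate must be finite and >= 0")
  value * 60
}
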