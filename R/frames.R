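#' PET frame schedule
#'
#' A frame schedule describes the acquisition frames of a PET measurement:
#' contiguous (or at least non-overlapping) half-open intervals
#' `[start, start + duration)`, in minutes from injection. Activity is
#' averaged within frames, so model predictions are evaluated either at the
#' frame midpoint or as the exact frame-integral average.
#'
#' @param start numeric vector of frame start times (minutes).
#' @param duration numeric vector of frame durations (minutes).
#' @param tol overlap tolerance (minutes).
#' @return An object of class `frame_schedule` with elements `start`,
#'   `duration`, `mid` (midpoints) and `end`.
#' @examples
#' fs <- frame_schedule(c(0, 1, 2), c(1, 1, 2))
#' fs$mid
#' @export
frame_schedule <- function(start, duration, tol = 1e-8) {
  start <- as.numeric(start)
  duration <- as.numeric(duration)
  if (length(start) != length(duration)) {
    stopf("start and duration lengths differ", class = "refsimba_schedule_error")
  }
  assert_finite(c(start, duration), "frame schedule")
  if (any(duration <= 0)) {
    stopf("frame durations must be positive", class = "refsimba_schedule_error")
  }
  if (is.unsorted(start)) {
    stopf("frame starts must be non-decreasing", class = "refsimba_schedule_error")
  }
  n <- length(start)
  if (n > 1 && any(start[-1] < start[-n] + duration[-n] - tol)) {
    stopf("frames overlap", class = "refsimba_schedule_error")
  }
  structure(
    list(start = start, duration = duration,
         mid = start + duration / 2, end = start + duration),
    class = "frame_schedule"
  )
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule: %d frames, %.1f-%.1f min>\n",
              length(x$start), x$start[1], x$end[length(x$end)]))
  invisible(x)
}

#' @export
length.frame_schedule <- function(x) length(x$start)

#' Default 93-minute HRRT-style frame schedule
#'
#' A 38-frame, 93-minute schedule with increasing frame durations
#' (9 x 10 s, 2 x 15 s, 3 x 20 s, 4 x 30 s, 4 x 60 s, 4 x 180 s, 12 x 360 s),
#' the style of grid used for long dynamic HRRT acquisitions.
#'
#' @return A [frame_schedule()].
#' @export
default_frames <- function() {
  durs <- c(rep(10, 9), rep(15, 2), rep(20, 3), rep(30, 4),
            rep(60, 4), rep(180, 4), rep(360, 12)) / 60
  frame_schedule(start = cumsum(c(0, durs[-length(durs)])), duration = durs)
}
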