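#' Time-activity curve
#'
#' The unit of measured PET data: a frame schedule together with
#' decay-corrected activity concentrations (one per frame) and optional
#' identifying metadata.
#'
#' @param frames a [frame_schedule()].
#' @param activity numeric vector of activities, one per frame (arbitrary
#'   consistent units; kBq/mL recommended — only ratios enter the kinetic
#'   parameters).
#' @param meta optional named list of metadata (subject, measurement,
#'   region, injected_dose, region_volume, ...).
#' @return An object of class `tac`.
#' @export
tac <- function(frames, activity, meta = list()) {
  if (!inherits(frames, "frame_schedule")) {
    stopf("frames must be a frame_schedule", class = "refsimba_schedule_error")
  }
  activity <- as.numeric(activity)
  if (length(activity) != length(frames$start)) {
    stopf("activity length (%d) does not match frame count (%d)",
          length(activity), length(frames$start),
          class = "refsimba_alignment_error")
  }
  assert_finite(activity, "activity")
  structure(list(frames = frames, activity = activity, meta = meta),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac: %d frames, peak %.3g>\n",
              length(x$frames$start), max(x$activity)))
  invisible(x)
}

# frame-duration weights (default) or uniform
#' @keywords internal
tac_weights <- function(frames, scheme = c("duration", "uniform")) {
  scheme <- match.arg(scheme)
  w <- if (scheme == "duration") frames$duration else rep(1, length(frames$start))
  w / mean(w)
}
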