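#' Acquisition calibration profile
#'
#' Bundles the physical scale of the optics and the time-lapse interval so
#' that pixel/frame displacements can be expressed in micrometres per hour.
#' Both values are instrument-specific and must be supplied by the user
#' (the scale of a x4 phase objective is not standardised across systems).
#'
#' @param microns_per_pixel Physical pixel size in micrometres (> 0).
#' @param minutes_per_frame Acquisition interval in minutes (> 0); the
#'   standard capture schedule used throughout is 8 min between frames.
#' @param label Optional free-text description of objective/instrument.
#'
#' @return An object of class `calibration_profile` with fields
#'   `microns_per_pixel`, `minutes_per_frame` and `label`.
#' @examples
#' calib <- calibration_profile(0.5, 8, "x4 PlanFluor")
#' px_per_frame_to_um_per_hour(1, calib)  # 3.75
#' @export
calibration_profile <- function(microns_per_pixel, minutes_per_frame,
                                label = "") {
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1 ||
      !is.finite(microns_per_pixel) || microns_per_pixel <= 0) {
    stop("`microns_per_pixel` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(minutes_per_frame) || length(minutes_per_frame) != 1 ||
      !is.finite(minutes_per_frame) || minutes_per_frame <= 0) {
    stop("`minutes_per_frame` must be a single positive number", call. = FALSE)
  }
  structure(
    list(microns_per_pixel = as.numeric(microns_per_pixel),
         minutes_per_frame = as.numeric(minutes_per_frame),
         label = as.character(label)),
    class = "calibration_profile"
  )
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat(sprintf("Calibration: %.6g um/px, %.6g min/frame (%.6g um/h per px/frame)",
              x$microns_per_pixel, x$minutes_per_frame,
              x$microns_per_pixel * 60 / x$minutes_per_frame))
  if (nzchar(x$label)) cat(" -", x$label)
  cat("\n")
  invisible(x)
}

stopifnot_calibration <- function(calib) {
  if (!inherits(calib, "calibration_profile")) {
    stop("`calib` must be a calibration_profile object", call. = FALSE)
  }
  invisible(calib)
}

#' Convert a displacement rate from px/frame to um/h
#'
#' The conversion factor is `microns_per_pixel * 60 / minutes_per_frame`:
#' at 0.5 um/px and 8 min/frame, 1 px/frame corresponds to 3.75 um/h.
#'
#' @param value Displacement rate(s) in pixels per frame (vectorised).
#' @param calib A [calibration_profile()].
#' @return Numeric vector in micrometres per hour.
#' @export
px_per_frame_to_um_per_hour <- function(value, calib) {
  stopifnot_calibration(calib)
  if (!is.numeric(value)) stop("`value` must be numeric", call. = FALSE)
  value * calib$microns_per_pixel * (60 / calib$minutes_per_frame)
}

#' Number of frames captured over a time-lapse schedule
#'
#' Both endpoints are imaged, so a capture of `duration_minutes` at
#' `interval_minutes` produces `floor(duration/interval) + 1` frames:
#' 4 h at 8-min intervals gives 31 frames.
#'
#' @param duration_minutes Total capture duration in minutes (>= 0).
#' @param interval_minutes Interval between frames in minutes (> 0).
#' @return Integer frame count.
#' @examples
#' expected_frame_count(240, 8)  # 31
#' @export
expected_frame_count <- function(duration_minutes, interval_minutes) {
  if (!is.numeric(interval_minutes) || any(interval_minutes <= 0)) {
    stop("`interval_minutes` must be positive", call. = FALSE)
  }
  if (!is.numeric(duration_minutes) || any(duration_minutes < 0)) {
    stop("`duration_minutes` must be non-negative", call. = FALSE)
  }
  as.integer(floor(duration_minutes / interval_minutes) + 1)
}
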