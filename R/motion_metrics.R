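# Physical motion indices: per-pair motion speed (MS) in um/h, its
# time-average MMS, and the capture start-condition check tied to
# confluency.

#' Motion record for one time-lapse capture
#'
#' Holds the per-pair MS series in both px/frame and um/h, the MMS, and
#' (optionally) the per-frame growth series.  `n_frames` frames yield
#' `n_frames - 1` consecutive pairs.
#'
#' @param ms_px_per_frame Numeric vector of per-pair mean displacement
#'   magnitudes in px/frame (`NA` marks pairs excluded for empty masks).
#' @param calibration A [calibration_profile()].
#' @param growth_series Optional per-frame growth percentages (length
#'   `n_frames`, or `n_frames - 1` when only the pairs' source frames
#'   were measured).
#' @param n_frames Frame count; defaults to `length(ms_px_per_frame)+1`.
#' @param paper_divisor Divide the MS sum by `n_frames` instead of the
#'   pair count when forming the MMS (see [mms()]).
#' @return Object of class `motion_record` with fields
#'   `ms_px_per_frame`, `ms_um_per_h`, `mms`, `growth_series`,
#'   `calibration`, `n_frames`.
#' @export
motion_record <- function(ms_px_per_frame, calibration, growth_series = NULL,
                          n_frames = length(ms_px_per_frame) + 1L,
                          paper_divisor = FALSE) {
  stopifnot_calibration(calibration)
  if (length(ms_px_per_frame) < 1) stop("no frame pairs", call. = FALSE)
  if (any(stats::na.omit(ms_px_per_frame) < 0)) {
    stop("motion speeds must be non-negative", call. = FALSE)
  }
  n_frames <- as.integer(n_frames)
  if (n_frames != length(ms_px_per_frame) + 1L) {
    stop("`n_frames` must equal the pair count + 1", call. = FALSE)
  }
  ms_um <- px_per_frame_to_um_per_hour(ms_px_per_frame, calibration)
  if (!is.null(growth_series)) {
    growth_series <- as.numeric(growth_series)
    if (!length(growth_series) %in% c(n_frames, n_frames - 1L)) {
      stop("`growth_series` length must be n_frames or n_frames - 1",
           call. = FALSE)
    }
  }
  structure(
    list(ms_px_per_frame = as.numeric(ms_px_per_frame),
         ms_um_per_h = ms_um,
         mms = mms(ms_um, n_frames = n_frames,
                   paper_divisor = paper_divisor),
         growth_series = growth_series,
         calibration = calibration,
         n_frames = n_frames),
    class = "motion_record"
  )
}

#' @export
print.motion_record <- function(x, ...) {
  cat(sprintf("Motion record: %d frames (%d pairs), MMS = %.2f um/h\n",
              x$n_frames, length(x$ms_um_per_h), x$mms))
  if (any(is.na(x$ms_um_per_h))) {
    cat(sprintf("  %d pair(s) excluded (empty mask)\n",
                sum(is.na(x$ms_um_per_h))))
  }
  if (!is.null(x$growth_series)) {
    cat(sprintf("  growth %.1f%% -> %.1f%%\n",
                x$growth_series[1], x$growth_series[length(x$growth_series)]))
  }
  invisible(x)
}

#' Per-pair motion-speed series of a sequence
#'
#' For each consecutive frame pair `(t, t+1)` computes the dense optical
#' flow, averages the displacement magnitude over the cell mask of frame
#' `t` (vectors originate at `t`), and converts to um/h.  Pairs whose
#' mask is empty yield `NA` with a warning and are later excluded from
#' the MMS.
#'
#' @param seq A [frame_sequence()].
#' @param masks List of 0/1 masks, one per frame (e.g. from
#'   [segment_sequence()]).
#' @param calib A [calibration_profile()].
#' @param params A [flow_params()].
#' @return Numeric vector of length `n_frames - 1`, MS in um/h.
#' @export
ms_series <- function(seq, masks, calib, params = flow_params()) {
  if (!inherits(seq, "frame_sequence")) {
    stop("`seq` must be a frame_sequence", call. = FALSE)
  }
  if (length(masks) != seq$n_frames) {
    stop("need exactly one mask per frame", call. = FALSE)
  }
  stopifnot_calibration(calib)
  out <- numeric(seq$n_frames - 1L)
  for (i in seq_len(seq$n_frames - 1L)) {
    fl <- dense_flow(seq$frames[[i]], seq$frames[[i + 1L]], params)
    mag <- withCallingHandlers(
      masked_mean_magnitude(fl, masks[[i]]),
      warning = function(w) {
        warning(sprintf("frame pair %d: %s", i, conditionMessage(w)),
                call. = FALSE)
        invokeRestart("muffleWarning")
      })
    out[i] <- px_per_frame_to_um_per_hour(mag, calib)
  }
  out
}

#' Mean motion speed (MMS) of an MS series
#'
#' By default the arithmetic mean over the available (non-missing) MS
#' values, i.e. the sum over pairs divided by the pair count.  The
#' originally described statistic divides the MS sum of an `n`-frame
#' capture by `n` rather than by the `n - 1` pairs; `paper_divisor =
#' TRUE` reproduces that convention (for 31 frames the two differ by the
#' factor 30/31).
#'
#' @param series MS values in um/h (`NA` entries are excluded with a
#'   warning).
#' @param n_frames Frame count of the capture; required when
#'   `paper_divisor = TRUE` and the series contains no `NA` hint
#'   (defaults to `length(series) + 1`).
#' @param paper_divisor Divide the sum by `n_frames` instead of the pair
#'   count.
#' @return MMS in um/h.
#' @export
mms <- function(series, n_frames = length(series) + 1L,
                paper_divisor = FALSE) {
  if (length(series) == 0) stop("empty MS series", call. = FALSE)
  if (all(is.na(series))) stop("all MS values are missing", call. = FALSE)
  if (any(is.na(series))) {
    warning(sprintf("%d missing MS value(s) excluded from the MMS",
                    sum(is.na(series))))
  }
  if (paper_divisor) {
    sum(series, na.rm = TRUE) / n_frames
  } else {
    mean(series, na.rm = TRUE)
  }
}

#' Sample-level MMS across dish locations
#'
#' The capture protocol images several randomly chosen locations per dish
#' (five in the standard protocol); the sample's MMS is the mean of the
#' per-location MMS values.
#'
#' @param location_mms Numeric vector of per-location MMS values (um/h).
#' @return Mean MMS in um/h.
#' @export
aggregate_sample_mms <- function(location_mms) {
  if (length(location_mms) == 0) stop("no location MMS values", call. = FALSE)
  mean(location_mms)
}

#' Check the capture start condition
#'
#' Collective motion is only a stable index when the capture starts at
#' roughly half confluency and the covered area stays near-flat over the
#' capture: at high confluency contact inhibition depresses the motion
#' over the 4 h window, and at low confluency it drifts upward.  PASS
#' requires the first-frame growth fraction inside `band` and the maximum
#' relative departure from it below `max_relative_change`; otherwise
#' WARN, always with diagnostics.
#'
#' @param growth Per-frame growth percentages (non-empty).
#' @param band Acceptable first-frame confluency band, in percent.
#' @param max_relative_change Maximum allowed `|g_t - g_1| / g_1`.
#' @return List with `status` ("PASS"/"WARN"), `start_percent`,
#'   `relative_change`, `band`, `max_relative_change`, `messages`.
#' @export
start_condition_check <- function(growth, band = c(40, 60),
                                  max_relative_change = 0.10) {
  if (length(growth) == 0) stop("empty growth series", call. = FALSE)
  g1 <- growth[1]
  rel <- if (g1 > 0) max(abs(growth - g1)) / g1 else Inf
  msgs <- character(0)
  if (g1 < band[1]) {
    msgs <- c(msgs, sprintf(
      "start confluency %.1f%% below %g%%: motion tends to drift upward",
      g1, band[1]))
  } else if (g1 > band[2]) {
    msgs <- c(msgs, sprintf(
      "start confluency %.1f%% above %g%%: contact inhibition depresses motion",
      g1, band[2]))
  }
  if (rel > max_relative_change) {
    msgs <- c(msgs, sprintf(
      "growth fraction changed by %.1f%% of its start value (limit %g%%)",
      100 * rel, 100 * max_relative_change))
  }
  list(status = if (length(msgs)) "WARN" else "PASS",
       start_percent = g1, relative_change = rel, band = band,
       max_relative_change = max_relative_change, messages = msgs)
}

#' Full motion analysis of one sequence
#'
#' Convenience pipeline: segment every frame, compute the per-pair MS
#' series and growth series, and assemble a [motion_record()].
#'
#' @param seq A [frame_sequence()].
#' @param calib A [calibration_profile()].
#' @param cv_params A [chan_vese_params()].
#' @param fl_params A [flow_params()].
#' @param masks Optional precomputed mask list (skips segmentation).
#' @param paper_divisor Passed to [motion_record()].
#' @param ... Further arguments to [segment_sequence()] (e.g. `cleanup`,
#'   `decimate`).
#' @return A [motion_record()].
#' @export
analyze_sequence <- function(seq, calib, cv_params = chan_vese_params(),
                             fl_params = flow_params(), masks = NULL,
                             paper_divisor = FALSE, ...) {
  if (is.null(masks)) masks <- segment_sequence(seq, cv_params, ...)
  ms_um <- ms_series(seq, masks, calib, fl_params)
  conv <- calib$microns_per_pixel * 60 / calib$minutes_per_frame
  motion_record(ms_px_per_frame = ms_um / conv, calibration = calib,
                growth_series = growth_series(masks),
                n_frames = seq$n_frames, paper_divisor = paper_divisor)
}
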