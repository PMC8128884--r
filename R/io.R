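# Reading and writing of image sequences, masks, flow fields and tabular
# results.  Frames are held as numeric matrices in [0, 1]; masks as 0/1
# integer matrices with 1 = cell.

#' Construct a frame sequence
#'
#' @param frames List of 2-D numeric matrices, all the same shape, in
#'   acquisition order.  Intensities must be finite.
#' @return Object of class `frame_sequence` with fields `frames`,
#'   `n_frames`, `height`, `width`.
#' @export
frame_sequence <- function(frames) {
  if (!is.list(frames) || length(frames) < 2) {
    stop("a frame sequence needs at least 2 frames", call. = FALSE)
  }
  for (f in frames) assert_matrix(f, "frames[[i]]")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must share the same height x width", call. = FALSE)
  }
  structure(
    list(frames = frames, n_frames = length(frames),
         height = dims[1, 1], width = dims[2, 1]),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("Frame sequence: %d frames of %d x %d px\n",
              x$n_frames, x$height, x$width))
  invisible(x)
}

# Convert an array as returned by readTIFF/readPNG to a [0,1] grayscale
# matrix.  RGB(A) is collapsed by Rec. 709 luminance; out-of-range float
# data is rescaled to [0,1].
as_gray_frame <- function(a) {
  if (length(dim(a)) == 3) {
    nc <- dim(a)[3]
    if (nc >= 3) {
      a <- 0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3]
    } else {
      a <- a[, , 1]
    }
  }
  a <- as.matrix(a)
  if (!all(is.finite(a))) stop("frame contains non-finite values", call. = FALSE)
  if (min(a) < 0 || max(a) > 1) {
    rng <- range(a)
    if (rng[2] > rng[1]) a <- (a - rng[1]) / (rng[2] - rng[1]) else a[] <- 0
  }
  a
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(img)) img <- list(img)
    lapply(img, as_gray_frame)
  } else if (ext == "png") {
    list(as_gray_frame(png::readPNG(path)))
  } else {
    stop(sprintf("unsupported image format: '%s'", ext), call. = FALSE)
  }
}

#' Read an ordered grayscale image sequence
#'
#' Accepts either a multi-page TIFF file or a directory of numbered
#' TIFF/PNG frames.  Directory frames are ordered by natural sort of the
#' file name (so `frame2` precedes `frame10`).  All frames are converted
#' to single-channel floating grayscale in `[0, 1]` regardless of source
#' bit depth; RGB input is collapsed by luminance.
#'
#' @param path Multi-page TIFF file, or directory containing the frames.
#' @param pattern Optional filename regular expression used when `path`
#'   is a directory (default: any `.tif/.tiff/.png`).
#' @return A [frame_sequence()].
#' @export
read_sequence <- function(path, pattern = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("path does not exist: '%s'", path), call. = FALSE)
  }
  if (dir.exists(path)) {
    if (is.null(pattern)) pattern <- "\\.(tif|tiff|png)$"
    files <- list.files(path, pattern = pattern, ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0) {
      stop(sprintf("no image files matching '%s' in '%s'", pattern, path),
           call. = FALSE)
    }
    files <- natural_sort(files)
    frames <- unlist(lapply(files, read_image_file), recursive = FALSE)
  } else {
    frames <- read_image_file(path)
  }
  if (length(frames) < 2) {
    stop("sequence has fewer than 2 frames; motion needs consecutive pairs",
         call. = FALSE)
  }
  frame_sequence(frames)
}

#' Write / read a binary cell mask as an 8-bit image
#'
#' Masks are stored as single-channel PNG or TIFF with background 0 and
#' cell 255; reading binarises at 0.5 so the round trip is lossless.
#'
#' @param mask 0/1 matrix (1 = cell).
#' @param path Output file; format chosen by extension (`.png`, `.tif`).
#' @return `write_mask` returns `path` invisibly; `read_mask` the 0/1
#'   integer matrix.
#' @export
write_mask <- function(mask, path) {
  assert_matrix(mask, "mask")
  img <- ifelse(mask > 0.5, 1, 0)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 8L)
  } else {
    stop("mask format must be png or tiff", call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- read_image_file(path)[[1]]
  out <- matrix(0L, nrow(m), ncol(m))
  out[m > 0.5] <- 1L
  out
}

#' Export / import a flow field as a 2-page 32-bit float TIFF
#'
#' Page 1 holds `u` (column displacement), page 2 `v` (row displacement),
#' both in px/frame.  TIFF float samples are stored on a `[0, 1]` scale,
#' so displacements are mapped through the fixed affine code
#' `(d + range) / (2 * range)`; the default range of 64 px/frame is far
#' beyond any physical cell displacement and the 32-bit mantissa keeps
#' the round trip accurate to ~1e-5 px.  Values outside the range are
#' clipped with a warning.
#'
#' @param flow A [flow_field()].
#' @param path TIFF output path.
#' @param range Half-width of the representable displacement interval
#'   (px/frame); must match between write and read.
#' @return `write_flow` returns `path` invisibly; `read_flow` the
#'   [flow_field()].
#' @export
write_flow <- function(flow, path, range = 64) {
  if (!inherits(flow, "flow_field")) stop("`flow` must be a flow_field",
                                          call. = FALSE)
  if (max(abs(flow$u), abs(flow$v)) > range) {
    warning("displacements beyond the representable range were clipped")
  }
  enc <- function(d) pmin(pmax((d + range) / (2 * range), 0), 1)
  tiff::writeTIFF(list(enc(flow$u), enc(flow$v)), path,
                  bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_flow
#' @export
read_flow <- function(path, range = 64) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (length(pages) != 2) stop("flow TIFF must have exactly 2 pages",
                               call. = FALSE)
  dec <- function(p) as.matrix(p) * (2 * range) - range
  flow_field(dec(pages[[1]]), dec(pages[[2]]))
}

#' Write a motion record to CSV (and read it back)
#'
#' One row per consecutive frame pair (pair index, MS in px/frame, MS in
#' um/h, growth fraction of the pair's first frame in %), followed by a
#' summary row carrying the MMS.  Values are written at full double
#' precision so a round trip reproduces the record exactly; calibration is
#' kept in `#`-prefixed header lines.
#'
#' @param record A [motion_record()].
#' @param path CSV output path.
#' @return `write_results` returns `path` invisibly; `read_results` a
#'   [motion_record()] equal to the one written.
#' @export
write_results <- function(record, path) {
  if (!inherits(record, "motion_record")) {
    stop("`record` must be a motion_record", call. = FALSE)
  }
  n_pairs <- length(record$ms_um_per_h)
  if (n_pairs == 0) stop("record has no frame pairs", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# microns_per_pixel=%s",
                     format_full(record$calibration$microns_per_pixel)), con)
  writeLines(sprintf("# minutes_per_frame=%s",
                     format_full(record$calibration$minutes_per_frame)), con)
  writeLines(sprintf("# n_frames=%d", record$n_frames), con)
  writeLines("row,pair_index,ms_px_per_frame,ms_um_per_h,growth_percent", con)
  growth <- record$growth_series
  if (is.null(growth)) growth <- rep(NA_real_, n_pairs)
  for (i in seq_len(n_pairs)) {
    writeLines(paste("pair", i, format_full(record$ms_px_per_frame[i]),
                     format_full(record$ms_um_per_h[i]),
                     format_full(growth[i]), sep = ","), con)
  }
  writeLines(paste("summary", "", "", format_full(record$mms), "", sep = ","),
             con)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get_hdr <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, "="), hdr)]
    as.numeric(sub(paste0("^# ", key, "="), "", ln[1]))
  }
  calib <- calibration_profile(get_hdr("microns_per_pixel"),
                               get_hdr("minutes_per_frame"))
  n_frames <- as.integer(get_hdr("n_frames"))
  body <- utils::read.csv(text = lines[!startsWith(lines, "#")],
                          stringsAsFactors = FALSE)
  pairs <- body[body$row == "pair", ]
  growth <- as.numeric(pairs$growth_percent)
  if (all(is.na(growth))) growth <- NULL
  motion_record(ms_px_per_frame = as.numeric(pairs$ms_px_per_frame),
                calibration = calib, growth_series = growth,
                n_frames = n_frames)
}

#' Render a displacement-vector overlay for visual QC
#'
#' Draws the frame as a grayscale raster with one arrow at every
#' `stride`-th masked pixel; arrow length is `scale` times the local
#' displacement.  Zero-length displacements are drawn as dots.  Intended
#' purely for eyeballing flow fields, not for measurement.
#'
#' @param frame 2-D intensity matrix in `[0, 1]`.
#' @param flow A [flow_field()] of the same shape.
#' @param mask 0/1 matrix of the same shape (arrows only where 1).
#' @param stride Grid spacing in pixels between arrows.
#' @param scale Arrow-length multiplier.
#' @param file Optional PNG output path; when given, the overlay is
#'   written there, otherwise it is drawn on the current device.
#' @return The file path (or `NULL` when drawing to the current device),
#'   invisibly.
#' @export
render_vector_overlay <- function(frame, flow, mask, stride = 16, scale = 2,
                                  file = NULL) {
  assert_matrix(frame, "frame")
  if (!inherits(flow, "flow_field")) stop("`flow` must be a flow_field",
                                          call. = FALSE)
  if (!all(dim(frame) == dim(flow$u)) || !all(dim(frame) == dim(mask))) {
    stop("frame, flow and mask shapes must agree", call. = FALSE)
  }
  h <- nrow(frame); w <- ncol(frame)
  if (!is.null(file)) {
    grDevices::png(file, width = w, height = h)
    on.exit(grDevices::dev.off())
  }
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot(NA, xlim = c(0.5, w + 0.5), ylim = c(h + 0.5, 0.5),
                 asp = 1, axes = FALSE, xlab = "", ylab = "",
                 xaxs = "i", yaxs = "i")
  graphics::rasterImage(pmin(pmax(frame, 0), 1),
                        0.5, h + 0.5, w + 0.5, 0.5, interpolate = FALSE)
  rows <- seq(1 + stride %/% 2, h, by = stride)
  cols <- seq(1 + stride %/% 2, w, by = stride)
  grid <- expand.grid(r = rows, c = cols)
  keep <- mask[cbind(grid$r, grid$c)] > 0.5
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) > 0) {
    u <- flow$u[cbind(grid$r, grid$c)] * scale
    v <- flow$v[cbind(grid$r, grid$c)] * scale
    len <- sqrt(u^2 + v^2)
    deg <- len < 1e-6
    if (any(deg)) {
      graphics::points(grid$c[deg], grid$r[deg], pch = 16, cex = 0.3,
                       col = "yellow")
    }
    if (any(!deg)) {
      graphics::arrows(grid$c[!deg], grid$r[!deg],
                       grid$c[!deg] + u[!deg], grid$r[!deg] + v[!deg],
                       length = 0.04, col = "yellow")
    }
  }
  invisible(file)
}
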