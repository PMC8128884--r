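# Internal array helpers shared by segmentation, optical flow and the
# synthetic generator.  All images are plain numeric matrices, row-major,
# origin top-left; u = column displacement, v = row displacement.

#' @keywords internal
assert_matrix <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a 2-D numeric matrix", arg), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  invisible(x)
}

# Shift a matrix by (dr, dc) with replicated (clamped) borders.
shift_clamp <- function(x, dr, dc) {
  h <- nrow(x); w <- ncol(x)
  ri <- pmin(pmax(seq_len(h) + dr, 1L), h)
  ci <- pmin(pmax(seq_len(w) + dc, 1L), w)
  x[ri, ci, drop = FALSE]
}

# Shift a matrix by (dr, dc) with toroidal wrap.
shift_wrap <- function(x, dr, dc) {
  h <- nrow(x); w <- ncol(x)
  ri <- ((seq_len(h) - 1L + dr) %% h) + 1L
  ci <- ((seq_len(w) - 1L + dc) %% w) + 1L
  x[ri, ci, drop = FALSE]
}

# Separable correlation with 1-D kernels (odd length, centre tap in the
# middle), replicated borders.  `ky` runs down rows, `kx` across columns.
sep_filter <- function(x, ky, kx) {
  ny <- (length(ky) - 1L) %/% 2L
  nx <- (length(kx) - 1L) %/% 2L
  out <- 0
  if (length(ky) == 1L) {
    out <- x * ky
  } else {
    out <- matrix(0, nrow(x), ncol(x))
    for (k in seq_along(ky)) {
      if (ky[k] != 0) out <- out + ky[k] * shift_clamp(x, k - 1L - ny, 0L)
    }
  }
  if (length(kx) == 1L) {
    return(out * kx)
  }
  res <- matrix(0, nrow(x), ncol(x))
  for (k in seq_along(kx)) {
    if (kx[k] != 0) res <- res + kx[k] * shift_clamp(out, 0L, k - 1L - nx)
  }
  res
}

# Normalised 1-D Gaussian kernel of radius n.
gauss_kernel <- function(n, sigma) {
  x <- (-n):n
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# Bilinear sampling of `img` at fractional (row, col) positions, clamped
# to the image domain.  `rows` and `cols` are equally-long vectors.
bilinear_sample <- function(img, rows, cols) {
  h <- nrow(img); w <- ncol(img)
  rows <- pmin(pmax(rows, 1), h)
  cols <- pmin(pmax(cols, 1), w)
  r0 <- pmin(floor(rows), h - 1L); c0 <- pmin(floor(cols), w - 1L)
  fr <- rows - r0; fc <- cols - c0
  i00 <- (c0 - 1) * h + r0
  img[i00]           * (1 - fr) * (1 - fc) +
    img[i00 + 1]     * fr       * (1 - fc) +
    img[i00 + h]     * (1 - fr) * fc +
    img[i00 + h + 1] * fr       * fc
}

# Bilinear resize to (h2, w2), pixel-centre aligned.
resize_bilinear <- function(img, h2, w2) {
  h <- nrow(img); w <- ncol(img)
  rows <- (seq_len(h2) - 0.5) * h / h2 + 0.5
  cols <- (seq_len(w2) - 0.5) * w / w2 + 0.5
  grid_r <- matrix(rows, h2, w2)
  grid_c <- matrix(cols, h2, w2, byrow = TRUE)
  matrix(bilinear_sample(img, as.numeric(grid_r), as.numeric(grid_c)), h2, w2)
}

# Natural ("version-number") sort for microscope frame exports such as
# frame2.tif, frame10.tif.
natural_sort <- function(x) {
  keyify <- function(s) {
    parts <- regmatches(s, gregexpr("[0-9]+|[^0-9]+", s))[[1]]
    nums <- suppressWarnings(as.numeric(parts))
    parts[!is.na(nums)] <- sprintf("%020.5f", nums[!is.na(nums)])
    paste(parts, collapse = "")
  }
  x[order(vapply(x, keyify, character(1)), x)]
}

# Full-precision number formatting for lossless CSV round-trips.
format_full <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}
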