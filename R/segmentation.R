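# Cell-area segmentation: Gaussian smoothing -> Sobel edge magnitude ->
# Chan-Vese active-contour binarisation.  The Chan-Vese evolution runs on
# the edge-magnitude image, where cell area is edge-rich (textured
# cytoplasm/membranes) and background is flat.

#' Smooth a frame with a 3x3 Gaussian kernel
#'
#' Separable Gaussian with unit-sum weights over a 3x3 support.  The
#' default `sigma = 0.8` is close to the best discrete Gaussian
#' realisable on that support.
#'
#' @param frame 2-D numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return Smoothed matrix of the same shape.
#' @export
smooth_frame <- function(frame, sigma = 0.8) {
  assert_matrix(frame, "frame")
  g <- gauss_kernel(1L, sigma)
  sep_filter(frame, g, g)
}

#' Sobel edge magnitude
#'
#' Applies the 3x3 Sobel kernels for horizontal and vertical derivatives
#' and combines them as `sqrt(Gx^2 + Gy^2)`.  Borders are handled by
#' replication, so a constant image maps to exactly zero everywhere.
#'
#' @param frame 2-D numeric matrix (normally the smoothed frame).
#' @return Non-negative matrix of the same shape.
#' @export
edge_magnitude <- function(frame) {
  assert_matrix(frame, "frame")
  gx <- sep_filter(frame, c(1, 2, 1), c(-1, 0, 1))
  gy <- sep_filter(frame, c(-1, 0, 1), c(1, 2, 1))
  sqrt(gx^2 + gy^2)
}

#' Chan-Vese segmentation parameters
#'
#' Weights of the two-phase piecewise-constant active-contour energy
#' `mu * Length(C) + nu * Area(inside) + lambda1 * int_inside (u0 - c1)^2
#' + lambda2 * int_outside (u0 - c2)^2`, plus the numerical controls of
#' the level-set evolution.  The default weights are the tuned values for
#' phase-contrast keratinocyte cultures (lambda1 = 1.2, lambda2 = 1.0,
#' nu = 0.02, mu = 0.8) and assume the input image is scaled to `[0, 1]`.
#'
#' @param lambda1,lambda2 Inside/outside data-fit weights (> 0).
#' @param nu Area weight (positive values shrink the inside phase).
#' @param mu Contour-length weight.
#' @param max_iterations Iteration cap for the level-set evolution.
#' @param tolerance Convergence threshold on the mean absolute level-set
#'   change per accepted iteration.
#' @param time_step Initial evolution step size; the solver backtracks
#'   (halves the step) whenever a step would increase the energy, so the
#'   recorded energy trace is non-increasing.
#' @param epsilon Regularisation width of the smoothed Heaviside/delta.
#' @param init Level-set initialisation.  `"threshold"` (default) seeds
#'   the level set with the image minus its Otsu threshold, which on
#'   edge-magnitude images reliably converges to the cell/background
#'   split; the classical `"checkerboard"` seeding tends to settle into
#'   a local minimum that traces individual texture ridges instead of
#'   whole cell regions (see the methods vignette).
#' @param rescale Rescale the input image to `[0, 1]` before evolving,
#'   keeping the energy weights on a fixed intensity scale.
#' @return Object of class `chan_vese_params`.
#' @export
chan_vese_params <- function(lambda1 = 1.2, lambda2 = 1.0, nu = 0.02,
                             mu = 0.8, max_iterations = 500L,
                             tolerance = 1e-4, time_step = 0.5,
                             epsilon = 1.0,
                             init = c("threshold", "checkerboard"),
                             rescale = TRUE) {
  if (lambda1 <= 0 || lambda2 <= 0) stop("lambda1 and lambda2 must be > 0",
                                         call. = FALSE)
  if (max_iterations < 1) stop("max_iterations must be >= 1", call. = FALSE)
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  if (time_step <= 0) stop("time_step must be > 0", call. = FALSE)
  structure(
    list(lambda1 = lambda1, lambda2 = lambda2, nu = nu, mu = mu,
         max_iterations = as.integer(max_iterations), tolerance = tolerance,
         time_step = time_step, epsilon = epsilon,
         init = match.arg(init), rescale = isTRUE(rescale)),
    class = "chan_vese_params"
  )
}

# Otsu threshold on a 256-bin histogram; used only for the optional
# "threshold" level-set initialisation.
otsu_threshold <- function(x) {
  rng <- range(x)
  if (rng[2] <= rng[1]) return(rng[1])
  h <- tabulate(pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * 256) + 1, 256),
                nbins = 256)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu_c <- cumsum(p * seq_len(256))
  mu_t <- mu_c[256]
  sigma_b <- (mu_t * omega - mu_c)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + k / 256 * (rng[2] - rng[1])
}

# Chan-Vese energy of a level set phi over image u0 (phi > 0 = inside).
# Plain-R mirror of the compiled evolution's energy, kept as an
# independent cross-check for tests.
cv_energy <- function(phi, u0, p, c1, c2) {
  H <- 0.5 * (1 + (2 / pi) * atan(phi / p$epsilon))
  hx <- shift_clamp(H, 0L, 1L) - H
  hy <- shift_clamp(H, 1L, 0L) - H
  p$mu * sum(sqrt(hx^2 + hy^2)) + p$nu * sum(H) +
    p$lambda1 * sum(H * (u0 - c1)^2) +
    p$lambda2 * sum((1 - H) * (u0 - c2)^2)
}

cv_region_means <- function(phi, u0, epsilon) {
  H <- 0.5 * (1 + (2 / pi) * atan(phi / epsilon))
  s1 <- sum(H); s2 <- sum(1 - H)
  c1 <- if (s1 > 0) sum(u0 * H) / s1 else mean(u0)
  c2 <- if (s2 > 0) sum(u0 * (1 - H)) / s2 else mean(u0)
  c(c1, c2)
}

#' Chan-Vese active-contour binarisation
#'
#' Evolves a level set by explicit gradient descent on the two-phase
#' Chan-Vese energy until the mean absolute change falls below
#' `params$tolerance` or `params$max_iterations` is reached.  Steps that
#' would increase the energy trigger step halving, so the recorded energy
#' trace is non-increasing by construction.  After convergence the phase
#' with the larger mean intensity of `img` is labelled "cell" (on an
#' edge-magnitude image the cell area is the edge-rich, bright phase).
#'
#' A constant input admits no two-phase split; the fit is then flagged
#' `degenerate` and carries an empty mask, with a warning.
#'
#' @param img 2-D numeric matrix to binarise (typically
#'   [edge_magnitude()] of a smoothed frame).
#' @param params A [chan_vese_params()].
#' @param init_phi Optional initial level set (matrix of the same shape),
#'   overriding `params$init`; used to warm-start consecutive frames.
#' @return Object of class `chan_vese_fit`: `mask` (0/1 integer matrix,
#'   1 = cell), `phi` (final level set), `energy` (non-increasing trace
#'   over accepted iterations), `iterations`, `converged`, `degenerate`.
#' @export
chan_vese_segment <- function(img, params = chan_vese_params(),
                              init_phi = NULL) {
  assert_matrix(img, "img")
  if (!inherits(params, "chan_vese_params")) {
    stop("`params` must be chan_vese_params", call. = FALSE)
  }
  h <- nrow(img); w <- ncol(img)
  rng <- range(img)
  if (rng[2] - rng[1] < 1e-12) {
    warning("constant image: no two-phase split; returning empty mask")
    return(structure(
      list(mask = matrix(0L, h, w), phi = matrix(-1, h, w),
           energy = numeric(0), iterations = 0L, converged = TRUE,
           degenerate = TRUE),
      class = "chan_vese_fit"
    ))
  }
  u0 <- if (params$rescale) (img - rng[1]) / (rng[2] - rng[1]) else img

  if (!is.null(init_phi)) {
    if (!all(dim(init_phi) == c(h, w))) {
      stop("`init_phi` shape must match the image", call. = FALSE)
    }
    phi <- init_phi
  } else if (params$init == "checkerboard") {
    phi <- outer(sin(pi / 5 * seq_len(h)), sin(pi / 5 * seq_len(w)))
  } else {
    phi <- 2 * (u0 - otsu_threshold(u0))
  }

  ev <- .cv_evolve(u0, phi, params$lambda1, params$lambda2, params$nu,
                   params$mu, params$epsilon, params$time_step,
                   params$tolerance, params$max_iterations)
  phi <- ev$phi
  trace <- ev$energy
  it <- ev$iterations
  converged <- ev$converged

  mask <- matrix(0L, h, w)
  mask[phi > 0] <- 1L
  n_in <- sum(mask)
  if (n_in > 0 && n_in < length(mask)) {
    if (mean(u0[mask == 1L]) < mean(u0[mask == 0L])) mask <- 1L - mask
  }
  structure(
    list(mask = mask, phi = phi, energy = trace, iterations = it,
         converged = converged, degenerate = FALSE),
    class = "chan_vese_fit"
  )
}

#' @export
print.chan_vese_fit <- function(x, ...) {
  cat(sprintf(
    "Chan-Vese fit: %d iterations, %s, cell fraction %.1f%%%s\n",
    x$iterations, if (x$converged) "converged" else "iteration cap",
    100 * mean(x$mask), if (x$degenerate) " [degenerate input]" else ""))
  invisible(x)
}

# Connected-component labels by minimum-label propagation (4-neighbour).
label_components <- function(mask) {
  lab <- matrix(Inf, nrow(mask), ncol(mask))
  lab[mask > 0.5] <- which(mask > 0.5)
  repeat {
    new <- pmin(lab,
                shift_clamp(lab, 1L, 0L), shift_clamp(lab, -1L, 0L),
                shift_clamp(lab, 0L, 1L), shift_clamp(lab, 0L, -1L))
    new[mask <= 0.5] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  lab[is.infinite(lab)] <- 0
  lab
}

#' Morphological cleanup of a binary mask
#'
#' Fills enclosed background holes and removes connected cell components
#' smaller than `min_size` pixels (4-connectivity).  Off by default in
#' the segmentation pipeline, since the basic procedure does not include
#' a cleanup pass.
#'
#' @param mask 0/1 matrix.
#' @param min_size Minimum component area kept, in pixels.
#' @param fill_holes Fill background regions not connected to the border.
#' @return Cleaned 0/1 integer matrix.
#' @export
clean_mask <- function(mask, min_size = 64, fill_holes = TRUE) {
  assert_matrix(mask, "mask")
  m <- matrix(0L, nrow(mask), ncol(mask))
  m[mask > 0.5] <- 1L
  if (fill_holes) {
    bg <- 1L - m
    reach <- matrix(0L, nrow(m), ncol(m))
    reach[1, ] <- bg[1, ]; reach[nrow(m), ] <- bg[nrow(m), ]
    reach[, 1] <- bg[, 1]; reach[, ncol(m)] <- bg[, ncol(m)]
    repeat {
      grown <- pmax(reach, shift_clamp(reach, 1L, 0L),
                    shift_clamp(reach, -1L, 0L), shift_clamp(reach, 0L, 1L),
                    shift_clamp(reach, 0L, -1L)) * bg
      if (identical(grown, reach)) break
      reach <- grown
    }
    m[bg == 1L & reach == 0L] <- 1L
  }
  if (min_size > 1) {
    lab <- label_components(m)
    sizes <- table(lab[lab > 0])
    drop <- as.numeric(names(sizes)[sizes < min_size])
    if (length(drop)) m[lab %in% drop] <- 0L
  }
  m
}

#' Segment every frame of a sequence
#'
#' Runs the three-step procedure (3x3 Gaussian smoothing, Sobel edge
#' magnitude, Chan-Vese binarisation) independently on each frame;
#' results are deterministic for identical inputs.
#'
#' @param seq A [frame_sequence()].
#' @param params A [chan_vese_params()].
#' @param sigma Smoothing sigma passed to [smooth_frame()].
#' @param cleanup Apply [clean_mask()] to each mask (off by default).
#' @param decimate Integer >= 1; when > 1 the edge image is downscaled by
#'   this factor before the level-set evolution and the mask is upscaled
#'   back, trading boundary precision for speed on large frames.
#' @param warm_start Reuse each frame's converged level set to initialise
#'   the next frame.  Off by default: a warm-started contour adapts only
#'   slowly to content that moved or grew between frames, biasing masks
#'   on anything but a static scene.  Enable only for sequences known to
#'   be near-static (it then saves most of the iterations).
#' @return List of 0/1 integer mask matrices, one per frame, with the
#'   per-frame iteration counts in attribute `"iterations"`.
#' @export
segment_sequence <- function(seq, params = chan_vese_params(), sigma = 0.8,
                             cleanup = FALSE, decimate = 1L,
                             warm_start = FALSE) {
  if (!inherits(seq, "frame_sequence")) {
    stop("`seq` must be a frame_sequence", call. = FALSE)
  }
  decimate <- as.integer(decimate)
  if (decimate < 1L) stop("`decimate` must be >= 1", call. = FALSE)
  masks <- vector("list", seq$n_frames)
  iters <- integer(seq$n_frames)
  phi_prev <- NULL
  for (i in seq_len(seq$n_frames)) {
    edge <- edge_magnitude(smooth_frame(seq$frames[[i]], sigma = sigma))
    if (decimate > 1L) {
      edge <- resize_bilinear(edge, max(2L, nrow(edge) %/% decimate),
                              max(2L, ncol(edge) %/% decimate))
    }
    fit <- chan_vese_segment(edge, params,
                             init_phi = if (warm_start) phi_prev else NULL)
    if (warm_start && !fit$degenerate) phi_prev <- fit$phi
    m <- fit$mask
    if (decimate > 1L) {
      m <- resize_bilinear(m + 0, seq$height, seq$width)
      m <- matrix(as.integer(m > 0.5), seq$height, seq$width)
    }
    if (cleanup) m <- clean_mask(m)
    masks[[i]] <- m
    iters[i] <- fit$iterations
  }
  attr(masks, "iterations") <- iters
  masks
}

#' Overall cells/colony growth of one mask
#'
#' Fraction of the image covered by the segmented cell area:
#' `100 * (cell pixels) / (total pixels)`, in percent.
#'
#' @param mask 0/1 matrix (1 = cell).
#' @return Percentage in `[0, 100]`.
#' @export
growth_fraction <- function(mask) {
  if (length(mask) == 0) stop("empty mask", call. = FALSE)
  assert_matrix(mask, "mask")
  100 * sum(mask > 0.5) / length(mask)
}

#' Growth-fraction series over a mask list
#'
#' @param masks Non-empty list of 0/1 matrices in frame order.
#' @return Numeric vector of percentages, one per frame.
#' @export
growth_series <- function(masks) {
  if (!is.list(masks) || length(masks) == 0) {
    stop("`masks` must be a non-empty list", call. = FALSE)
  }
  vapply(masks, growth_fraction, numeric(1))
}
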