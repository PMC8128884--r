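# Synthetic phase-contrast-like time-lapse generator.  Colonies are
# blob-shaped regions of band-limited sinusoidal texture on a
# near-uniform background, advanced each frame by a known displacement
# (evaluated analytically at displaced coordinates, so sub-pixel motion
# is exact), with ground-truth masks and displacement fields recorded
# before noise.

#' Simulation specification
#'
#' Defines one synthetic capture.  Defaults emulate the standard imaging
#' condition the pipeline targets: a field at ~50% confluency holding a
#' few discrete, loosely connected colonies, imaged every 8 min at
#' 0.5 um/px, with near-flat growth over the capture.
#'
#' @param height,width Frame size in pixels.
#' @param n_frames Number of frames (>= 2).
#' @param colony_count Number of colonies.
#' @param initial_confluency First-frame cell coverage, percent (0-100,
#'   exclusive).
#' @param confluency_drift Percentage-point increase in coverage over the
#'   whole capture (kept small: coverage is near-flat at ~50%
#'   confluency over a 4-h window).
#' @param speed_um_per_h Imposed collective speed (>= 0); with the
#'   default calibration, 30 um/h corresponds to 8 px/frame.
#' @param direction_mode `"uniform"` (all colonies share one random
#'   heading), `"per-colony-random"`, or `"swirl"` (tangential around
#'   the image centre).
#' @param texture_scale Base wavelength of the fine texture band in
#'   pixels; the colony texture combines dense fine-scale granularity at
#'   this wavelength (edge-rich, as segmentation needs) with coarser
#'   sinusoidal structure at 2.4-6.4x this scale (trackable by the flow
#'   pyramid under large displacements).
#' @param noise_sd Additive Gaussian intensity noise (image scale is
#'   `[0, 1]`).
#' @param calibration A [calibration_profile()].
#' @param seed Integer seed; output is deterministic given the spec.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(height = 256L, width = 256L, n_frames = 10L,
                            colony_count = 3L, initial_confluency = 50,
                            confluency_drift = 1, speed_um_per_h = 30,
                            direction_mode = c("uniform",
                                               "per-colony-random",
                                               "swirl"),
                            texture_scale = 5, noise_sd = 0.01,
                            calibration = calibration_profile(0.5, 8),
                            seed = 1L) {
  if (n_frames < 2) stop("`n_frames` must be >= 2", call. = FALSE)
  if (initial_confluency <= 0 || initial_confluency >= 100) {
    stop("`initial_confluency` must be in (0, 100)", call. = FALSE)
  }
  if (speed_um_per_h < 0) stop("`speed_um_per_h` must be >= 0", call. = FALSE)
  stopifnot_calibration(calibration)
  structure(
    list(height = as.integer(height), width = as.integer(width),
         n_frames = as.integer(n_frames),
         colony_count = as.integer(colony_count),
         initial_confluency = initial_confluency,
         confluency_drift = confluency_drift,
         speed_um_per_h = speed_um_per_h,
         direction_mode = match.arg(direction_mode),
         texture_scale = texture_scale, noise_sd = noise_sd,
         calibration = calibration, seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

# Toroidal offset of every pixel from a (possibly fractional) centre.
torus_offsets <- function(h, w, cy, cx) {
  dy <- ((seq_len(h) - cy + h / 2) %% h) - h / 2
  dx <- ((seq_len(w) - cx + w / 2) %% w) - w / 2
  list(dy = matrix(dy, h, w), dx = matrix(dx, h, w, byrow = TRUE))
}

#' Simulate a textured time-lapse sequence with known truth
#'
#' Colony shapes are star-convex blobs (radius modulated by low-order
#' harmonics) whose texture is a colony-anchored sum of random-phase
#' sinusoids; each frame evaluates texture and shape at coordinates
#' displaced by the accumulated motion, so brightness constancy holds
#' exactly under the imposed sub-pixel displacements.  Motion wraps
#' toroidally, keeping coverage constant apart from the imposed growth
#' drift.  Truth masks and per-pair displacement fields are recorded
#' before noise is added.
#'
#' @param spec A [simulation_spec()].
#' @param keep_flows Record per-pair truth displacement fields (set
#'   `FALSE` to save memory on large cohorts).
#' @return List with `sequence` (a [frame_sequence()]) and `truth`: a
#'   list holding `masks` (per-frame 0/1 matrices), `flows` (per-pair
#'   [flow_field()]s, or `NULL`), `true_mean_speed` (um/h),
#'   `true_growth_series` (percent per frame), and the `spec`.
#' @export
simulate_sequence <- function(spec, keep_flows = TRUE) {
  if (!inherits(spec, "simulation_spec")) {
    stop("`spec` must be a simulation_spec", call. = FALSE)
  }
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width; k <- spec$colony_count
  Tn <- spec$n_frames
  conv <- spec$calibration$microns_per_pixel *
    60 / spec$calibration$minutes_per_frame
  s_px <- spec$speed_um_per_h / conv

  # per-colony areas and base radii filling the initial confluency
  wts <- stats::runif(k, 0.8, 1.25)
  areas <- wts / sum(wts) * spec$initial_confluency / 100 * h * w
  radius <- sqrt(areas / pi)

  # centres: rejection sampling for toroidal separation, best effort
  cx <- numeric(k); cy <- numeric(k)
  for (i in seq_len(k)) {
    best <- NULL; best_d <- -Inf
    for (try in 1:60) {
      px <- stats::runif(1, 1, w); py <- stats::runif(1, 1, h)
      if (i == 1) { best <- c(px, py); break }
      dx <- abs(px - cx[seq_len(i - 1)]); dx <- pmin(dx, w - dx)
      dy <- abs(py - cy[seq_len(i - 1)]); dy <- pmin(dy, h - dy)
      margin <- min(sqrt(dx^2 + dy^2) -
                      (radius[i] + radius[seq_len(i - 1)]) * 1.05)
      if (margin > best_d) { best_d <- margin; best <- c(px, py) }
      if (margin > 0) break
    }
    cx[i] <- best[1]; cy[i] <- best[2]
  }

  # shape harmonics and texture components
  shapes <- lapply(seq_len(k), function(i) {
    list(m = 2:4, amp = stats::runif(3, 0, 0.12) / (1:3),
         phase = stats::runif(3, 0, 2 * pi))
  })
  # Two texture bands per colony.  Fine band: a pair of orthogonal
  # triangle waves — piecewise-linear, so the gradient magnitude inside
  # the colony is bounded away from zero almost everywhere, mimicking the
  # dense granular edge response of phase-contrast cytoplasm that the
  # edge-based segmentation relies on.  Coarse band: random-phase
  # sinusoids at 2.4-6.4x the base wavelength, giving the flow pyramid
  # trackable structure for large displacements.
  textures <- lapply(seq_len(k), function(i) {
    ori <- stats::runif(1, 0, 2 * pi)
    J <- 5L
    lam_c <- exp(stats::runif(J, log(2.4 * spec$texture_scale),
                              log(6.4 * spec$texture_scale)))
    ori_c <- stats::runif(J, 0, 2 * pi)
    list(fine_ori = ori,
         fine_lam = spec$texture_scale * c(0.86, 1.14),
         fine_phase = stats::runif(2, 0, 2 * pi),
         fine_amp = 0.11,
         kx = cos(ori_c) * 2 * pi / lam_c,
         ky = sin(ori_c) * 2 * pi / lam_c,
         phase = stats::runif(J, 0, 2 * pi),
         amp = rep(0.05, J))
  })

  # headings
  theta <- switch(spec$direction_mode,
    "uniform" = rep(stats::runif(1, 0, 2 * pi), k),
    "per-colony-random" = stats::runif(k, 0, 2 * pi),
    "swirl" = atan2(cy - h / 2, cx - w / 2) + pi / 2
  )
  vx <- s_px * cos(theta); vy <- s_px * sin(theta)

  # growth factor per frame from the confluency ramp
  conf_t <- spec$initial_confluency +
    spec$confluency_drift * (seq_len(Tn) - 1) / max(Tn - 1, 1)
  g_t <- sqrt(conf_t / spec$initial_confluency)

  bg <- 0.08
  frames <- vector("list", Tn)
  masks <- vector("list", Tn)
  flows <- if (keep_flows) vector("list", Tn - 1L) else NULL
  pair_speed_px <- numeric(Tn - 1L)
  noise <- lapply(seq_len(Tn), function(t) {
    matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
  })

  for (t in seq_len(Tn)) {
    frame <- matrix(bg, h, w)
    mask <- matrix(0L, h, w)
    ut <- matrix(0, h, w); vt <- matrix(0, h, w)
    for (i in seq_len(k)) {
      off <- torus_offsets(h, w, cy[i] + (t - 1) * vy[i],
                           cx[i] + (t - 1) * vx[i])
      rho <- sqrt(off$dx^2 + off$dy^2)
      ang <- atan2(off$dy, off$dx)
      sh <- shapes[[i]]
      R <- radius[i] * g_t[t] *
        (1 + sh$amp[1] * cos(2 * ang + sh$phase[1]) +
           sh$amp[2] * cos(3 * ang + sh$phase[2]) +
           sh$amp[3] * cos(4 * ang + sh$phase[3]))
      inside <- rho <= R
      if (!any(inside)) next
      tx <- textures[[i]]
      tri <- function(t) (2 / pi) * asin(sin(t))
      ax <- cos(tx$fine_ori) * off$dx + sin(tx$fine_ori) * off$dy
      ay <- -sin(tx$fine_ori) * off$dx + cos(tx$fine_ori) * off$dy
      tex <- 0.5 +
        tx$fine_amp * tri(2 * pi / tx$fine_lam[1] * ax + tx$fine_phase[1]) +
        tx$fine_amp * tri(2 * pi / tx$fine_lam[2] * ay + tx$fine_phase[2])
      for (j in seq_along(tx$amp)) {
        tex <- tex + tx$amp[j] *
          sin(tx$kx[j] * off$dx + tx$ky[j] * off$dy + tx$phase[j])
      }
      frame[inside] <- pmin(pmax(tex[inside], 0.02), 0.98)
      mask[inside] <- 1L
      ut[inside] <- vx[i]; vt[inside] <- vy[i]
    }
    masks[[t]] <- mask
    frames[[t]] <- pmin(pmax(frame + noise[[t]], 0), 1)
    if (t < Tn) {
      sel <- mask > 0L
      pair_speed_px[t] <- if (any(sel)) mean(sqrt(ut[sel]^2 + vt[sel]^2))
        else 0
      if (keep_flows) flows[[t]] <- flow_field(ut, vt)
    }
  }

  truth <- list(
    masks = masks, flows = flows,
    true_mean_speed = px_per_frame_to_um_per_hour(mean(pair_speed_px),
                                                  spec$calibration),
    true_growth_series = vapply(masks, function(m) 100 * mean(m), numeric(1)),
    spec = spec
  )
  list(sequence = frame_sequence(frames), truth = truth)
}

#' Simulate a cohort with a speed-to-PDT link
#'
#' Generates one sequence per spec and attaches a synthetic population
#' doubling time `pdt_link(true speed) + Gaussian noise`, emulating a
#' cohort in which faster-moving cultures proliferate faster (lower
#' PDT).  The ground-truth pairs are retained so a pipeline estimate of
#' the speed-PDT association can be compared against the truth.
#'
#' @param specs List of [simulation_spec()]s (>= 4); per-sample seeds are
#'   derived from `seed` so the cohort is reproducible as a whole.
#' @param pdt_link Monotone function mapping true speed (um/h) to PDT
#'   (days).  The default decreasing link spreads PDT over roughly 2-3.5
#'   days across speeds of 15-60 um/h.
#' @param pdt_noise_sd Gaussian sd of the PDT noise, days.
#' @param seed Integer master seed.
#' @param keep_flows Passed to [simulate_sequence()].
#' @return List with `samples` (per-sample list of `sequence`, `truth`,
#'   `pdt`) and `table` (`data.frame` with `sample`, `true_speed`,
#'   `pdt`).
#' @export
make_cohort <- function(specs, pdt_link = function(v) 4 - v / 30,
                        pdt_noise_sd = 0.15, seed = 1L,
                        keep_flows = FALSE) {
  if (!is.list(specs) || length(specs) < 4) {
    stop("need at least 4 simulation specs", call. = FALSE)
  }
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  sub_seeds <- sample.int(2^31 - 1, length(specs))
  pdt_noise <- stats::rnorm(length(specs), 0, pdt_noise_sd)
  samples <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    sp$seed <- sub_seeds[i]
    sim <- simulate_sequence(sp, keep_flows = keep_flows)
    samples[[i]] <- list(
      sequence = sim$sequence, truth = sim$truth,
      pdt = pdt_link(sp$speed_um_per_h) + pdt_noise[i]
    )
  }
  tab <- data.frame(
    sample = seq_along(specs),
    true_speed = vapply(specs, function(s) s$speed_um_per_h, numeric(1)),
    pdt = vapply(samples, function(s) s$pdt, numeric(1))
  )
  list(samples = samples, table = tab)
}

#' Intersection over union of two masks
#'
#' Segmentation-quality measure `|A & B| / |A | B|`; defined as 1 when
#' both masks are empty.
#'
#' @param mask_a,mask_b 0/1 matrices of equal shape.
#' @return Ratio in `[0, 1]`.
#' @export
iou <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b))) {
    stop("mask shapes must agree", call. = FALSE)
  }
  a <- mask_a > 0.5; b <- mask_b > 0.5
  uni <- sum(a | b)
  if (uni == 0) return(1)
  sum(a & b) / uni
}
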