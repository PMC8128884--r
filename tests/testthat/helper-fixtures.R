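# Shared fixture builders and independent oracles.

# Deterministic textured test image: mixed-wavelength sinusoids, values
# well inside [0, 1].  Used for flow tests where any trackable pattern
# will do.
textured_image <- function(h = 96, w = 96, seed = 1) {
  set.seed(seed)
  X <- matrix(seq_len(w), h, w, byrow = TRUE)
  Y <- matrix(seq_len(h), h, w)
  img <- matrix(0.5, h, w)
  for (j in 1:8) {
    lam <- exp(stats::runif(1, log(4), log(24)))
    th <- stats::runif(1, 0, 2 * pi)
    ph <- stats::runif(1, 0, 2 * pi)
    img <- img + 0.05 * sin(2 * pi / lam * (cos(th) * X + sin(th) * Y) + ph)
  }
  img
}

# Brute-force dense 2-D convolution/correlation with replicated borders;
# the independent oracle for the separable filters used in the package.
brute_correlate3 <- function(img, kern) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      acc <- 0
      for (a in -1:1) {
        for (b in -1:1) {
          ii <- min(max(i + a, 1), h)
          jj <- min(max(j + b, 1), w)
          acc <- acc + kern[a + 2, b + 2] * img[ii, jj]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Classical no-ties Spearman formula, the brute-force oracle:
# rho = 1 - 6 * sum(d^2) / (n (n^2 - 1)).
spearman_formula <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

default_calib <- function() calibration_profile(0.5, 8)

# Small, fast simulation spec for module-level tests; any field can be
# overridden.
small_spec <- function(...) {
  args <- list(height = 96L, width = 96L, n_frames = 4L, colony_count = 2L,
               speed_um_per_h = 7.5, seed = 99L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_spec, args)
}
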