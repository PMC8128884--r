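test_that("polynomial expansion reproduces an exact quadratic signal", {
  h <- 40; w <- 40
  Cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  Rr <- matrix(seq_len(h), h, w)
  # f(x, y) = 3 + 0.2 x + 0.1 y - 0.004 x^2 + 0.006 y^2 + 0.003 xy with
  # x = column, y = row; a quadratic is fitted exactly away from borders
  f <- 3 + 0.2 * Cc + 0.1 * Rr - 0.004 * Cc^2 + 0.006 * Rr^2 +
    0.003 * Cc * Rr
  e <- poly_expansion(f, n = 2, sigma = 1.1)
  interior <- 5:35
  expect_equal(e$r1[interior, interior], f[interior, interior],
               tolerance = 1e-8)
  # local derivatives: d f / dx = 0.2 - 0.008 x + 0.003 y
  expect_equal(e$b1[interior, interior],
               (0.2 - 0.008 * Cc + 0.003 * Rr)[interior, interior],
               tolerance = 1e-8)
  expect_equal(e$a11[interior, interior],
               matrix(-0.004, h, w)[interior, interior], tolerance = 1e-8)
  expect_equal(e$a22[interior, interior],
               matrix(0.006, h, w)[interior, interior], tolerance = 1e-8)
})

test_that("identical frames give essentially zero flow", {
  img <- textured_image(96, 96, seed = 2)
  fl <- dense_flow(img, img)
  expect_lt(mean(sqrt(fl$u^2 + fl$v^2)), 0.05)
})

test_that("integer rigid shifts are recovered in the interior", {
  img <- textured_image(96, 96, seed = 5)
  # roll the image content two columns to the right
  shifted <- img[, c(95, 96, 1:94)]
  fl <- dense_flow(img, shifted)
  interior <- 16:80
  expect_equal(mean(fl$u[interior, interior]), 2, tolerance = 0.2)
  expect_lt(abs(mean(fl$v[interior, interior])), 0.1)
  # diagonal (1, 1) shift: mean magnitude near sqrt(2)
  diag_sh <- img[c(96, 1:95), c(96, 1:95)]
  fl2 <- dense_flow(img, diag_sh)
  mag <- sqrt(fl2$u^2 + fl2$v^2)
  expect_equal(mean(mag[interior, interior]), sqrt(2),
               tolerance = 0.1 * sqrt(2))
})

test_that("sub-pixel to multi-pixel shifts recovered within 15%", {
  for (sh in c(0.5, 1.5, 3)) {
    # speed chosen so the generator imposes exactly `sh` px/frame
    spec <- simulation_spec(height = 128L, width = 128L, n_frames = 2L,
                            colony_count = 2L, confluency_drift = 0,
                            speed_um_per_h = 3.75 * sh, seed = 21L)
    sim <- simulate_sequence(spec)
    fl <- dense_flow(sim$sequence$frames[[1]], sim$sequence$frames[[2]])
    est <- masked_mean_magnitude(fl, sim$truth$masks[[1]])
    expect_lt(abs(est - sh) / sh, 0.15)
  }
})

test_that("horizontal flip negates u and preserves magnitudes", {
  spec <- simulation_spec(height = 128L, width = 128L, n_frames = 2L,
                          confluency_drift = 0, speed_um_per_h = 15,
                          seed = 31L)
  sim <- simulate_sequence(spec)
  f1 <- sim$sequence$frames[[1]]; f2 <- sim$sequence$frames[[2]]
  fl <- dense_flow(f1, f2)
  flip <- function(m) m[, ncol(m):1]
  fl_f <- dense_flow(flip(f1), flip(f2))
  sel <- sim$truth$masks[[1]] > 0
  m1 <- mean(sqrt(fl$u[sel]^2 + fl$v[sel]^2))
  m2 <- mean(sqrt(fl_f$u[, ncol(f1):1][sel]^2 + fl_f$v[, ncol(f1):1][sel]^2))
  expect_equal(m2, m1, tolerance = 0.02 * m1)
  expect_equal(mean(fl_f$u[, ncol(f1):1][sel]), -mean(fl$u[sel]),
               tolerance = 0.02 * max(abs(mean(fl$u[sel])), 0.1))
})

test_that("flow is deterministic and validates its inputs", {
  img <- textured_image(64, 64, seed = 9)
  sh <- img[, c(64, 1:63)]
  fl1 <- dense_flow(img, sh)
  fl2 <- dense_flow(img, sh)
  expect_identical(fl1, fl2)
  expect_error(dense_flow(img, img[1:32, ]), "shapes")
  expect_error(dense_flow(img[1:8, 1:8], img[1:8, 1:8]), "window")
})

test_that("masked mean magnitude averages all vectors, sub-pixel included", {
  h <- 20; w <- 20
  mask <- matrix(0L, h, w); mask[5:14, 5:16] <- 1L  # 120 px, even count
  unif <- flow_field(matrix(3, h, w), matrix(4, h, w))
  expect_equal(masked_mean_magnitude(unif, mask), 5)
  zero <- flow_field(matrix(0, h, w), matrix(0, h, w))
  expect_equal(masked_mean_magnitude(zero, mask), 0)
  # half the masked pixels at 0.4 px, half at 1.6 px: mean 1.0 shows the
  # sub-pixel half is not discarded
  u <- matrix(0, h, w)
  sel <- which(mask == 1L)
  u[sel[seq(1, length(sel), by = 2)]] <- 0.4
  u[sel[seq(2, length(sel), by = 2)]] <- 1.6
  half <- flow_field(u, matrix(0, h, w))
  expect_equal(masked_mean_magnitude(half, mask), 1.0)
  # all-ones mask equals the unmasked mean
  rnd <- flow_field(matrix(rnorm(h * w), h, w), matrix(rnorm(h * w), h, w))
  expect_equal(masked_mean_magnitude(rnd, matrix(1L, h, w)),
               mean(sqrt(rnd$u^2 + rnd$v^2)))
  expect_warning(res <- masked_mean_magnitude(unif, matrix(0L, h, w)),
                 "empty mask")
  expect_true(is.na(res))
})
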