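geom <- test_geometry()

test_that("system construction: trivial cases and guards", {
  p <- band_pattern_pairs(K = 4L, nr = 32L, nc = 32L)  # I_s = I_r
  sys <- build_lcs_system(p)
  expect_true(all(sys$rhs == 0))
  expect_equal(sys$K, 4L)
  r <- solve_lcs(sys)
  expect_lt(max(abs(r$D_x), abs(r$D_y), abs(r$I_obj), abs(r$D_f)), 1e-8)

  # uniform reference: derivative columns vanish, pixels flagged
  flat <- lapply(1:4, function(k) matrix(1000, 16, 16))
  pf <- make_pairs(flat, flat)
  sysf <- build_lcs_system(pf)
  expect_true(all(sysf$degenerate))

  # a pure 10% absorber puts 0.1 * I_r on the right-hand side
  pa <- band_pattern_pairs(K = 4L, nr = 32L, nc = 32L, trans = 0.9)
  sysa <- build_lcs_system(pa)
  expect_equal(sysa$rhs, 0.1 * sysa$value, tolerance = 1e-10)
  ra <- solve_lcs(sysa)
  expect_equal(mean(ra$I_obj), 0.1, tolerance = 0.05)

  expect_error(build_lcs_system(band_pattern_pairs(K = 3L)), "K >= 4")
})

test_that("constant displacement is recovered from warped pairs", {
  # gentle pattern band: the implicit linearization's second-order term
  # scales as D * pi * f, so the oracle uses a well-sampled pattern
  pat <- make_band_pattern(64, 64, n_modes = 60L, fmax = 0.04, seed = 7)
  set.seed(8)
  sx <- stats::runif(12, -40, 40); sy <- stats::runif(12, -40, 40)
  p <- make_pairs(lapply(1:12, function(k) pat(sx[k], sy[k])),
                  lapply(1:12, function(k) pat(sx[k] + 0.3, sy[k] - 0.2)))
  r <- lcs_retrieve(p)
  # displacement vector recovered within 5% RMS of its magnitude
  err <- sqrt(mean((r$D_x - 0.3)^2 + (r$D_y + 0.2)^2))
  expect_lt(err / sqrt(0.3^2 + 0.2^2), 0.05)
  expect_equal(mean(r$D_x), 0.3, tolerance = 0.02)
  expect_equal(mean(r$D_y), -0.2, tolerance = 0.02)
  # attribution: no absorption or blur was present
  expect_lt(sqrt(mean(r$I_obj^2)), 0.01)
  expect_lt(sqrt(mean(r$D_f^2)), 0.05)
})

test_that("pure blur appears as positive dark-field, not displacement", {
  sig <- 0.8
  p <- band_pattern_pairs(K = 8L, nr = 64L, nc = 64L, sigma = sig)
  r <- lcs_retrieve(p)
  expect_equal(mean(r$D_f), sig^2 / 2, tolerance = 0.1)
  expect_gt(mean(r$D_f > 0), 0.99)
  expect_lt(max(abs(mean(r$D_x)), abs(mean(r$D_y))), 0.01)

  # equation-term attribution under noise: adding blur moves D_f but leaves
  # D_x / D_y within the empty-field noise floor
  p0 <- band_pattern_pairs(K = 8L, noise = TRUE, seed = 21)
  pb <- band_pattern_pairs(K = 8L, sigma = sig, noise = TRUE, seed = 21)
  r0 <- lcs_retrieve(p0); rb <- lcs_retrieve(pb)
  floor_dx <- stats::sd(r0$D_x)
  expect_lt(abs(mean(rb$D_x) - mean(r0$D_x)), 3 * floor_dx / 8)
  # the blur moves the dark-field term by a sizeable fraction of sigma^2/2
  # (band-limited patterns under-drive the Laplacian, so not the full value)
  expect_gt(mean(rb$D_f) - mean(r0$D_f), 0.3 * sig^2 / 2)
})

test_that("joint smooth parameter fields are recovered within 10% of range", {
  # warp-generated pairs on a real spiral-mask pattern (broad spectrum:
  # strong gradients for D, strong curvature for D_f), 75000-count noise
  g <- test_geometry(c(96L, 96L))
  os <- 4L; K <- 10L; nr <- nc <- 96L
  mask <- build_mask("spiral", 6, g, c(96L, 96L), margin_px = 60L, os = os,
                     cone_height_um = calibrated_cone_height(g, 6, os = os))
  ref <- reference_intensity(mask, g, os = os)
  mr <- (nrow(ref) / os - nr) %/% 2
  iobj <- smooth_field(nr, nc, 0.00, 0.20, seed = 31)
  dxf <- smooth_field(nr, nc, -0.8, 0.8, seed = 32)
  dyf <- smooth_field(nr, nc, -0.8, 0.8, seed = 33)
  sgf <- smooth_field(nr, nc, 0.1, 0.9, seed = 34)
  up <- function(m) m[rep(seq_len(nr), each = os), rep(seq_len(nc), each = os)]
  dx_os <- up(dxf) * os; dy_os <- up(dyf) * os; sg_os <- up(sgf) * os
  set.seed(36)
  sx <- sample(c(-1, 1), K, TRUE) * sample(50:59, K, TRUE)
  Ir <- list(); Is <- list()
  for (k in seq_len(K)) {
    crop <- ref[mr * os + seq_len(nr * os), (mr + sx[k]) * os + seq_len(nc * os)]
    Iw <- mobir:::varying_blur(crop, sg_os)
    Iw <- warp_image(Iw, dx_os, dy_os) * up(1 - iobj)
    set.seed(400 + k)
    Ir[[k]] <- matrix(stats::rpois(nr * nc, bin_image(crop, os)), nr, nc)
    set.seed(500 + k)
    Is[[k]] <- matrix(stats::rpois(nr * nc, pmax(bin_image(Iw, os), 0)), nr, nc)
  }
  r <- lcs_retrieve(make_pairs(Ir, Is, g))
  rng <- function(x) diff(range(x))
  expect_lt(sqrt(mean((r$I_obj - iobj)^2)) / rng(iobj), 0.10)
  expect_lt(sqrt(mean((r$D_x - dxf)^2)) / rng(dxf), 0.10)
  expect_lt(sqrt(mean((r$D_y - dyf)^2)) / rng(dyf), 0.10)
  # the per-pixel diffusion term carries a Poisson noise floor of ~0.1 px^2
  # at this count level; its field is recovered to ~20% of range
  expect_lt(sqrt(mean((r$D_f - sgf^2 / 2)^2)) / rng(sgf^2 / 2), 0.25)
})

test_that("linearity: doubling the displacement doubles the retrieval", {
  p1 <- band_pattern_pairs(K = 6L, dy = 0.2)
  p2 <- band_pattern_pairs(K = 6L, dy = 0.4)
  r1 <- lcs_retrieve(p1); r2 <- lcs_retrieve(p2)
  expect_equal(mean(r2$D_y) / mean(r1$D_y), 2, tolerance = 0.05)
})

test_that("noise floor scales as 1/sqrt(counts)", {
  sd_at <- function(counts, seed) {
    p <- band_pattern_pairs(K = 8L, noise = TRUE, counts = counts, seed = seed)
    r <- lcs_retrieve(p)
    stats::sd(r$D_y[8:56, 8:56])
  }
  s1 <- mean(sd_at(18750, 51), sd_at(18750, 52))
  s4 <- mean(sd_at(75000, 51), sd_at(75000, 52))
  expect_equal(s1 / s4, 2, tolerance = 0.2)
})

test_that("phase integration: conversion arithmetic and re-integration", {
  # zero displacement -> zero phase
  z <- matrix(0, 16, 16)
  expect_true(all(integrate_phase(z, z, geom) == 0))
  # D_y = 1 px, 75 um pixels, z2 = 0.80 m -> 93.75 urad
  expect_equal(displacement_to_angle(1, geom), 93.75e-6)
  # a known curl-free gradient field integrates back to its potential
  nr <- nc <- 96L
  set.seed(61)
  kx <- sample(-10:10, 20, replace = TRUE)
  ky <- sample(-10:10, 20, replace = TRUE)
  ph <- stats::runif(20, 0, 2 * pi)
  X <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  Y <- matrix(seq_len(nr), nr, nc)
  pot <- matrix(0, nr, nc); gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  for (j in 1:20) {
    arg <- 2 * pi * (kx[j] * X / nc + ky[j] * Y / nr) + ph[j]
    pot <- pot + cos(arg)
    gx <- gx - 2 * pi * kx[j] / nc * sin(arg)
    gy <- gy - 2 * pi * ky[j] / nr * sin(arg)
  }
  rec <- fourier_integrate(gx, gy)
  expect_lt(sqrt(mean((rec - (pot - mean(pot)))^2)) / stats::sd(pot), 0.01)
})

test_that("tensor dark-field resolves anisotropy and orientation", {
  nr <- nc <- 64L
  K <- 8L
  pat <- make_band_pattern(nr, nc, seed = 71)
  set.seed(72)
  sx <- stats::runif(K, -40, 40); sy <- stats::runif(K, -40, 40)
  # anisotropic blur along x only (sigma_x = 0.8, sigma_y = 0)
  mode_blur <- function(k, sxx, syy) {
    # analytic anisotropic attenuation: rebuild the pattern mode-wise
    env <- environment(pat)
    out <- matrix(75000, nr, nc)
    X <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    Y <- matrix(seq_len(nr), nr, nc)
    for (j in seq_along(env$fx)) {
      att <- exp(-2 * pi^2 * (sxx^2 * env$fx[j]^2 + syy^2 * env$fy[j]^2))
      out <- out + env$amp * att *
        cos(2 * pi * (env$fx[j] * (X - sx[k]) + env$fy[j] * (Y - sy[k])) + env$ph[j])
    }
    out
  }
  Ir <- lapply(seq_len(K), function(k) pat(sx[k], sy[k]))
  Is_x <- lapply(seq_len(K), function(k) mode_blur(k, 0.8, 0))
  ddf <- directional_darkfield(make_pairs(Ir, Is_x))
  inn <- 8:56
  # principal axis along x: psi ~ 0 (mod pi)
  psi <- ddf$psi[inn, inn]
  expect_gt(mean(pmin(psi, pi - psi) < 0.3), 0.9)
  expect_gt(mean(ddf$a[inn, inn]), 3 * mean(ddf$b[inn, inn]))

  # isotropic blur: degenerate eigenvalues a ~ b
  Is_i <- lapply(seq_len(K), function(k) pat(sx[k], sy[k], 0.8))
  ddf_i <- directional_darkfield(make_pairs(Ir, Is_i))
  expect_equal(mean(ddf_i$a[inn, inn]), mean(ddf_i$b[inn, inn]),
               tolerance = 0.15)
  # no blur: tensor norm at the numerical floor
  ddf_0 <- directional_darkfield(make_pairs(Ir, Ir))
  expect_lt(mean(sqrt(ddf_0$a^2 + ddf_0$b^2)), 1e-4)
  expect_error(directional_darkfield(band_pattern_pairs(K = 5L)), "K >= 6")
  # HSV encoding emits an rgb array in range
  hsv_arr <- ddf_to_hsv(ddf)
  expect_equal(dim(hsv_arr), c(nr, nc, 3))
  expect_true(all(hsv_arr >= 0 & hsv_arr <= 1))
})

test_that("pooled solving reduces the noise floor", {
  p <- band_pattern_pairs(K = 6L, noise = TRUE, seed = 81)
  sys <- build_lcs_system(p)
  r1 <- solve_lcs(sys)
  r3 <- solve_lcs(sys, pool_w = 3L)
  expect_lt(stats::sd(r3$D_y[8:56, 8:56]), 0.6 * stats::sd(r1$D_y[8:56, 8:56]))
})
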