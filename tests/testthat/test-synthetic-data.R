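geom <- test_geometry()

test_that("phantom thickness maps match their closed forms", {
  grid <- sample_grid(geom, c(96L, 96L))
  # wire: max thickness = diameter on the axis
  w <- phantom_thickness("wire", grid, dims = list(diameter = 1.0))
  expect_equal(max(w$thickness), 1.0, tolerance = 1e-3)
  # horizontal wire: D0_y antisymmetric about the axis, D0_x ~ 0
  d0 <- theoretical_displacement(w, geom)
  expect_lt(max(abs(d0$D0_x)), 1e-9)
  expect_equal(d0$D0_y, -d0$D0_y[nrow(d0$D0_y):1, ], tolerance = 1e-6)

  # sphere chord at r = 3 mm from center of a 12 mm sphere: 2 sqrt(36 - 9)
  gbig <- sample_grid(geom, c(450L, 450L))
  s <- phantom_thickness("sphere", gbig)
  co <- mobir:::grid_coords_mm(gbig)
  j <- which.min(abs(co$x - 3)); i <- which.min(abs(co$y))
  expect_equal(s$thickness[i, j], 2 * sqrt(6^2 - 3^2), tolerance = 0.01)
  # sphere interior displacement matches the analytic chord derivative
  mc <- material_constants("nylon")
  r_mm <- 3
  slope <- -2 * r_mm / sqrt(6^2 - r_mm^2)  # d/dr of 2 sqrt(R^2-r^2)
  alpha <- mc$delta * slope                # thickness mm / transverse mm
  expect_d0 <- alpha * geom$d_sample_detector / (geom$pixel_size * 1e-6)
  d0s <- theoretical_displacement(s, geom)
  expect_equal(d0s$D0_x[i, j], expect_d0, tolerance = 0.02)

  # cube: constant thickness equal to the side over its footprint
  cbe <- phantom_thickness("cube", grid, dims = list(side = 1.5))
  expect_equal(max(cbe$thickness), 1.5)
  expect_setequal(unique(as.vector(cbe$thickness)), c(0, 1.5))

  # fractal: full dynamic range 0..max height
  j1 <- phantom_thickness("julia", grid, dims = list(width = 2.5, height = 1.4))
  expect_equal(max(j1$thickness), 5)
  expect_equal(min(j1$thickness), 0)

  # head phantom: thickness between 1 and 5 over the support
  sl <- phantom_thickness("shepp_logan", grid,
                          dims = list(width = 2.2, height = 2.6))
  sup <- sl$thickness > 0
  expect_equal(range(sl$thickness[sup]), c(1, 5), tolerance = 1e-6)

  expect_error(phantom_thickness("banana", grid), "unknown")
})

test_that("transmission screens follow the projection approximation", {
  grid <- sample_grid(geom, c(8L, 8L))
  t0 <- mobir:::new_thickness_map(matrix(0, 8, 8), "nylon", grid$pitch_um, "flat")
  scr <- screen_from_thickness(t0, geom)
  expect_true(all(scr$transmission == 1))
  expect_true(all(scr$phase == 0))
  # Beer-Lambert: doubling thickness squares the transmission
  t1 <- mobir:::new_thickness_map(matrix(2, 8, 8), "nylon", grid$pitch_um, "s1")
  t2 <- mobir:::new_thickness_map(matrix(4, 8, 8), "nylon", grid$pitch_um, "s2")
  expect_equal(screen_from_thickness(t2, geom)$transmission,
               screen_from_thickness(t1, geom)$transmission^2)
  # 5 mm nylon at 8.6 keV against the constants table
  t5 <- mobir:::new_thickness_map(matrix(5, 2, 2), "nylon", grid$pitch_um, "s5")
  mu <- material_constants("nylon")$mu_per_m
  expect_equal(screen_from_thickness(t5, geom)$transmission[1, 1],
               exp(-mu * 5e-3))
  expect_error(material_constants("unobtainium"), "no optical constants")
})

test_that("forward imaging: flat field, Poisson statistics, identity warp", {
  os <- 2L
  flat <- matrix(geom$mean_counts, 64 * os, 64 * os)
  img <- forward_image(flat, NULL, geom, os = os, noise = FALSE)
  expect_equal(img, matrix(geom$mean_counts, 64, 64))
  # noise on: per-pixel variance ~ mean over many pixels
  imgn <- forward_image(flat, NULL, geom, os = os, noise = TRUE, seed = 4)
  expect_equal(mean(imgn), geom$mean_counts, tolerance = 0.01)
  expect_equal(var(as.vector(imgn)), geom$mean_counts, tolerance = 0.05)
  # zero-thickness sample: identical to the reference
  opt0 <- list(transmission = matrix(1, 64 * os, 64 * os),
               dx_px = matrix(0, 64 * os, 64 * os),
               dy_px = matrix(0, 64 * os, 64 * os))
  expect_equal(forward_image(flat, opt0, geom, os = os, noise = FALSE), img)
})

test_that("acquire_series: shift protocol, determinism, margin guard", {
  h <- 30
  mask <- build_mask("spiral", 5, geom, c(48L, 48L), margin_px = 160L,
                     os = 2L, cone_height_um = h)
  p <- acquire_series(mask, NULL, geom, K = 10L, shift_axes = "x",
                      seed = 12, os = 2L, field_px = c(48L, 48L))
  expect_length(p$Ir, 10)
  expect_true(all(p$shifts[, 2] == 0))
  expect_true(all(abs(p$shifts[, 1]) >= 50 & abs(p$shifts[, 1]) <= 150))
  p2 <- acquire_series(mask, NULL, geom, K = 10L, shift_axes = "x",
                       seed = 12, os = 2L, field_px = c(48L, 48L))
  expect_identical(p$shifts, p2$shifts)
  expect_identical(p$Ir, p2$Ir)
  pxy <- acquire_series(mask, NULL, geom, K = 6L, shift_axes = "xy",
                        seed = 5, os = 2L, field_px = c(48L, 48L))
  expect_true(all(abs(pxy$shifts) >= 50 & abs(pxy$shifts) <= 150))
  # zero-shift single pair reproduces the unshifted reference
  p0 <- acquire_series(mask, NULL, geom, K = 1L, shift_axes = "x",
                       shift_range = c(0L, 0L), seed = 1, os = 2L,
                       field_px = c(48L, 48L), noise = FALSE)
  ref <- reference_intensity(mask, geom, os = 2L)
  mr <- (nrow(ref) / 2L - 48L) %/% 2L
  expect_equal(p0$Ir[[1]],
               bin_image(ref[mr * 2L + 1:96, mr * 2L + 1:96], 2L))
  # a mask without margin cannot host 150 px shifts
  small <- build_mask("spiral", 5, geom, c(48L, 48L), margin_px = 10L,
                      os = 2L, cone_height_um = h)
  expect_error(acquire_series(small, NULL, geom, K = 2L, os = 2L,
                              field_px = c(48L, 48L)), "margin")
})

test_that("energy conservation and membrane-plane magnification", {
  h <- 30
  mask <- build_mask("spiral", 5, geom, c(64L, 64L), margin_px = 160L,
                     os = 2L, cone_height_um = h)
  ref <- reference_intensity(mask, geom, os = 2L)
  mr <- (nrow(ref) / 2L - 64L) %/% 2L
  means <- sapply(c(0L, 60L, -120L), function(s)
    mean(bin_image(ref[mr * 2L + 1:128, (mr + s) * 2L + 1:128], 2L)))
  expect_lt(diff(range(means)) / mean(means), 1e-3)

  # one cone of physical size s at the membrane spans s*M/pixel detector px
  px_mem <- plane_pitch_um(geom, geom$d_source_membrane)
  d_um <- 12 * px_mem  # 12 detector px across at the membrane plane
  pts <- mobir:::new_point_set(30 * px_mem, 30 * px_mem, d_um,
                               c(60, 60) * px_mem, "random")
  m1 <- rasterize_mask(pts, list(type = "cone", height = 40),
                       grid_pitch = px_mem / 4)
  I <- bin_image(reference_intensity(m1, geom, os = 4L, source_blur = FALSE), 4L)
  span_px <- sum(I[30, ] < max(I) * (1 - 1e-6))
  expect_equal(span_px, 12, tolerance = 0.2)
})

test_that("warp and Fresnel forward models agree on the pattern displacement", {
  # a periodic sinusoidal phase grating bends the beam by a displacement
  # field dy(y) = D0 sin(2 pi y / P); wave-optically simulated pairs,
  # retrieved with the implicit system, must show the displacement the
  # ray-optical warp model prescribes
  # the oversampling must resolve the refracted wavefront: the deflection
  # alpha needs cells < lambda / (2 alpha), i.e. os = 12 here
  os <- 12L
  nf <- 64L
  h <- 30
  mask <- build_mask("spiral", 8, geom, c(nf, nf), margin_px = 160L, os = os,
                     cone_height_um = h)
  grid <- sample_grid(geom, c(nf, nf), os = os)
  co <- mobir:::grid_coords_mm(grid)
  P_mm <- 16 * plane_pitch_um(geom, geom$d_source_sample) / 1000  # 16 px
  thick <- matrix(0.4 * (1 + cos(2 * pi * co$y / P_mm)), grid$nr, grid$nc)
  grating <- mobir:::new_thickness_map(thick, "nylon", grid$pitch_um, "grating")
  opt <- mobir:::sample_optics(grating, geom)
  dy0 <- bin_image(opt$dy_px, os)
  expect_gt(max(abs(dy0)), 0.1)  # informative displacement scale
  K <- 6L
  set.seed(13)
  sx <- sample(c(-1L, 1L), K, TRUE) * sample(50:150, K)
  mr <- (nrow(mask$thickness) / os - nf) %/% 2
  Ir <- list(); Is <- list()
  for (k in seq_len(K)) {
    crop <- mask$thickness[mr * os + seq_len(nf * os),
                           (mr + sx[k]) * os + seq_len(nf * os)]
    Ir[[k]] <- fresnel_image(crop, "sio2", NULL, geom, os = os)
    Is[[k]] <- fresnel_image(crop, "sio2", grating, geom, os = os)
  }
  r <- lcs_retrieve(make_pairs(Ir, Is, geom))
  scale_fit <- sum(r$D_y * dy0) / sum(dy0^2)
  expect_equal(scale_fit, 1, tolerance = 0.2)
})

test_that("image-pair series round-trips through TIFF + manifest", {
  h <- 30
  mask <- build_mask("spiral", 5, geom, c(32L, 32L), margin_px = 160L,
                     os = 2L, cone_height_um = h)
  p <- acquire_series(mask, NULL, geom, K = 4L, seed = 3, os = 2L,
                      field_px = c(32L, 32L))
  d <- file.path(tempdir(), "pairs_io")
  write_pairs(p, d)
  p2 <- read_pairs(d)
  expect_equal(p2$Ir, p$Ir, tolerance = 1e-5)
  expect_equal(unname(as.matrix(p2$shifts)), unname(as.matrix(p$shifts)))
  unlink(d, recursive = TRUE)
})
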