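test_that("random points: uniform density, hard core, determinism, infeasibility", {
  # single point degenerate case stays in bounds
  p1 <- gen_random_points(1, c(100, 50), seed = 3)
  expect_true(p1$x >= 0 && p1$x <= 100 && p1$y >= 0 && p1$y <= 50)

  # 1000 points on 1x1 mm^2: quadrat counts match the uniform expectation
  ps <- gen_random_points(1000, c(1000, 1000), min_separation = 0, seed = 42)
  qx <- cut(ps$x, seq(0, 1000, by = 250))
  qy <- cut(ps$y, seq(0, 1000, by = 250))
  counts <- table(qx, qy)
  expect_equal(sum(counts), 1000)
  # chi-squared against uniform quadrat occupancy should not reject wildly
  chi <- sum((counts - 1000 / 16)^2 / (1000 / 16))
  expect_lt(chi, qchisq(0.999, df = 15))

  # hard core is honoured
  ps2 <- gen_random_points(200, c(1000, 1000), min_separation = 40, seed = 1)
  dmat <- as.matrix(dist(cbind(ps2$x, ps2$y)))
  diag(dmat) <- Inf
  expect_gte(min(dmat), 40)

  # identical seed => bit-identical points
  a <- gen_random_points(50, c(500, 500), min_separation = 10, seed = 9)
  b <- gen_random_points(50, c(500, 500), min_separation = 10, seed = 9)
  expect_identical(a, b)

  # infeasible packing fails loudly
  expect_error(gen_random_points(2, c(10, 10), min_separation = 1000),
               "diagonal")
  expect_error(gen_random_points(500, c(100, 100), min_separation = 20,
                                 max_tries = 50), "over-dense")
})

test_that("hexagonal lattice has pitch-spaced neighbours and the analytic density", {
  p <- 20
  ps <- gen_hexagonal_points(p, c(1000, 1000))
  d <- as.matrix(dist(cbind(ps$x, ps$y)))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_equal(max(abs(nn - p)), 0, tolerance = 1e-9)
  # interior density -> 2/(sqrt(3) p^2), counted on a large field
  inner <- ps$x > 100 & ps$x < 900 & ps$y > 100 & ps$y < 900
  dens <- sum(inner) / (800 * 800)
  expect_equal(dens, 2 / (sqrt(3) * p^2), tolerance = 0.05)
  # row/column count within one row of the extent-based expectation
  ps2 <- gen_hexagonal_points(p, c(10 * p, 10 * p))
  n_rows <- length(unique(round(ps2$y, 6)))
  expect_lte(abs(n_rows - ceiling(10 * p / (p * sqrt(3) / 2))), 1)
  # degenerate: pitch beyond the extent still yields one point
  expect_gte(length(gen_hexagonal_points(5000, c(100, 100))$x), 1)
})

test_that("square grid has exact counts and density", {
  p <- 10
  ps <- gen_square_points(p, c(5 * p, 3 * p))
  expect_equal(length(ps$x), 6 * 4)  # corners inclusive
  big <- gen_square_points(p, c(1000, 1000))
  inner <- big$x > 100 & big$x < 900 & big$y > 100 & big$y < 900
  expect_equal(sum(inner) / (800 * 800), 1 / p^2, tolerance = 0.05)
  expect_error(gen_square_points(-1, c(10, 10)))
})

test_that("Vogel spiral follows r = c sqrt(k), theta = k * golden angle", {
  ps <- gen_vogel_spiral_points(2, scale_c = 1, extent = c(10, 10),
                                center = c(5, 5))
  # k = 0 at the center
  expect_equal(ps$x[1], 5); expect_equal(ps$y[1], 5)
  # k = 1 at r = 1, theta ~ 137.5078 deg
  expect_equal(ps$x[2] - 5, -0.7373689, tolerance = 1e-6)
  expect_equal(ps$y[2] - 5, 0.6754903, tolerance = 1e-6)
  # asymptotic areal density 1/(pi c^2)
  cc <- 10
  ps2 <- gen_vogel_spiral_points(20000, cc, extent = c(4000, 4000))
  inner <- (ps2$x - 2000)^2 + (ps2$y - 2000)^2 < 1000^2
  expect_equal(sum(inner) / (pi * 1000^2), 1 / (pi * cc^2), tolerance = 0.05)
})

test_that("rasterization: profiles, volumes and guards", {
  # empty point set + hole profile = uniform plate
  empty <- mobir:::new_point_set(numeric(0), numeric(0), numeric(0),
                                 c(100, 100), "random")
  m0 <- rasterize_mask(empty, list(type = "hole", plate_thickness = 30),
                       material = "ni", grid_pitch = 1)
  expect_true(all(m0$thickness == 30))

  # single cone: apex height, zero outside d/2, volume ~ (pi/12) d^2 h
  one <- mobir:::new_point_set(50, 50, 20, c(100, 100), "random")
  m1 <- rasterize_mask(one, list(type = "cone", height = 8), grid_pitch = 0.5)
  expect_equal(max(m1$thickness), 8, tolerance = 0.05)
  xc <- (col(m1$thickness) - 0.5) * 0.5
  yc <- (row(m1$thickness) - 0.5) * 0.5
  far <- sqrt((xc - 50)^2 + (yc - 50)^2) > 10.5
  expect_true(all(m1$thickness[far] == 0))
  vol <- sum(m1$thickness) * 0.5^2
  expect_equal(vol, pi / 12 * 20^2 * 8, tolerance = 0.02)

  # aliasing guard names the diameter
  expect_error(rasterize_mask(one, list(type = "cone", height = 8),
                              grid_pitch = 10), "grid_pitch")
})

test_that("mask TIFF + JSON round trip preserves the model", {
  pts <- gen_vogel_spiral_points(200, 20, c(400, 400))
  m <- rasterize_mask(pts, list(type = "cone", height = 5), grid_pitch = 2)
  f <- file.path(tempdir(), "mask_roundtrip.tif")
  write_mask(m, f)
  m2 <- read_mask(f)
  expect_equal(m2$thickness, m$thickness, tolerance = 1e-6)
  expect_equal(m2$topology_tag, "spiral")
  expect_equal(m2$profile$height, 5)
  unlink(c(f, paste0(f, ".json")))
})

test_that("orientation content: lattices anisotropic, spiral/random isotropic", {
  g <- test_geometry()
  h <- 50
  ent <- sapply(c("random", "hexagonal", "regular", "spiral"), function(tp) {
    m <- build_mask(tp, 6, g, c(160L, 160L), margin_px = 4L, os = 4L,
                    cone_height_um = h, seed = 3)
    I <- bin_image(reference_intensity(m, g, os = 4L), 4L)
    gradient_stats(I)$orientation_entropy
  })
  # quasi-random patterns carry more orientation entropy than lattices
  expect_gt(min(ent["random"], ent["spiral"]), ent["regular"])
  expect_gte(ent["spiral"], ent["hexagonal"] - 0.05)
  # spiral entropy within 2% of the random mask's
  expect_lt(abs(ent["spiral"] - ent["random"]) / ent["random"], 0.02)
})
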