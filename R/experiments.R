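## Experiment drivers: the computational protocols of the study, from mask
## construction through retrieval to the metric tables. Each driver is
## deterministic given its seed and returns plain data.frames ready to write
## as CSV.

#' The Xeuss-like geometry preset used throughout the study
#'
#' 0.33 / 0.55 / 1.35 m source-membrane/sample/detector planes, 75 um pixels,
#' 8.6 keV, 50 um source spot, 75000 counts per pixel.
#' @param detector_shape detector field used for the run
#' @export
xeuss_geometry <- function(detector_shape = c(514L, 1030L)) {
  acquisition_geometry(detector_shape = detector_shape)
}

#' Calibrate the study's cone height at the design spacing
#'
#' One cone height is used for all topologies and sizes (the study fixes the
#' modulation amplitude and varies only the arrangement): the height that
#' gives the spiral mask at `spacing_px` a noise-free reference visibility of
#' `target`.
#'
#' @param geometry an [acquisition_geometry()]
#' @param spacing_px design peak-to-peak spacing (detector px)
#' @param field_px field used for the calibration render
#' @param os oversampling factor
#' @param target reference visibility std/mean
#' @return cone height in micrometres
#' @export
calibrated_cone_height <- function(geometry, spacing_px = 4, field_px = c(128L, 128L),
                                   os = 4L, target = 0.15) {
  m <- build_mask("spiral", spacing_px, geometry, field_px, margin_px = 8L, os = os)
  mc <- calibrate_mask_visibility(m, geometry, os = os, target = target)
  mc$profile$height
}

#' Build a study phantom scaled to a desk-scale field
#'
#' The phantom dimensions are quoted for the full 514 x 1030 px detector;
#' reduced-field runs keep the scene composition by scaling the transverse
#' dimensions with the field (relative to the full detector height) while
#' projected thicknesses keep their design values. A cap guarantees a
#' sample-free border (needed by the sensitivity windows).
#'
#' @param shape phantom tag, see [phantom_thickness()]
#' @param grid a [sample_grid()] for the run's field
#' @param geometry an [acquisition_geometry()]
#' @param fit maximum fraction of the field the footprint may span
#' @param smooth_um edge-rounding scale (um); the default 60 um reflects the
#'   fabrication resolution of printed/machined phantoms and keeps edge
#'   refraction within the displacement range the implicit retrieval can
#'   represent
#' @export
study_phantom <- function(shape, grid, geometry, fit = 0.85, smooth_um = 60) {
  full_h_mm <- 514 * plane_pitch_um(geometry, geometry$d_source_sample) / 1000
  field_mm <- c(w = grid$nc * grid$pitch_um / 1000,
                h = grid$nr * grid$pitch_um / 1000)
  s <- as.numeric(field_mm["h"]) / full_h_mm
  cap <- function(dims_wh) {
    f <- min(1, fit * field_mm["w"] / dims_wh[1], fit * field_mm["h"] / dims_wh[2])
    f
  }
  dims <- switch(shape,
    wire = list(diameter = 1.5 * s),
    sphere = list(diameter = 12 * s * cap(c(12 * s, 12 * s))),
    cube = list(side = 7 * s * cap(c(7 * s, 7 * s))),
    torus = {
      f <- cap(c(13 * s, 13 * s))
      list(outer = 13 * s * f, inner = 3 * s * f, max_thickness = 3)
    },
    shepp_logan = {
      f <- cap(c(13 * s, 18 * s))
      list(width = 13 * s * f, height = 18 * s * f)
    },
    julia = {
      f <- cap(c(18 * s, 10 * s))
      list(width = 18 * s * f, height = 10 * s * f)
    },
    stop("unknown phantom shape '", shape, "'"))
  phantom_thickness(shape, grid, dims = dims, smooth_um = smooth_um)
}

#' Simulate one pair series and retrieve it
#'
#' The workhorse behind every experiment: build the mask at the design
#' spacing, acquire K shifted reference/sample pairs, solve the LCS system.
#'
#' @param topology mask topology tag
#' @param sample `mobi_thickness` on the `os` grid of `field_px` (or NULL)
#' @param geometry an [acquisition_geometry()]
#' @param spacing_px design modulation spacing (detector px)
#' @param cone_height_um modulator height (um), typically from
#'   [calibrated_cone_height()]
#' @param K pairs
#' @param shift_axes "x" or "xy"
#' @param field_px detector field `c(rows, cols)`
#' @param os oversampling
#' @param seed master seed (drives mask randomness and noise)
#' @param margin_px mask margin for shifts
#' @return list with `retrieval`, `pairs`, `mask`
#' @export
run_retrieval <- function(topology, sample, geometry, spacing_px = 4,
                          cone_height_um, K = 10L, shift_axes = "x",
                          field_px = c(256L, 256L), os = 4L, seed = 1L,
                          margin_px = 160L) {
  mask <- build_mask(topology, spacing_px, geometry, field_px,
                     margin_px = margin_px, os = os,
                     cone_height_um = cone_height_um,
                     seed = derive_seed(seed, 101L))
  pairs <- acquire_series(mask, sample, geometry, K = K,
                          shift_axes = shift_axes, seed = seed, os = os,
                          field_px = field_px)
  list(retrieval = lcs_retrieve(pairs), pairs = pairs, mask = mask)
}

#' Modulation-size sweep
#'
#' NRMSE of the retrieved vertical displacement of the fractal phantom
#' against its theoretical map, for each topology across peak-to-peak
#' spacings, with two-axis membrane shifts. Reports the per-topology argmin.
#'
#' @param geometry an [acquisition_geometry()]
#' @param sizes_px spacings to sweep (detector px)
#' @param topologies mask topologies
#' @param field_px detector field
#' @param K pairs per run
#' @param os oversampling
#' @param seed master seed
#' @param target_visibility calibration target for the fixed cone height
#' @param sample_shape phantom used (fractal by default)
#' @return list with `table` (topology, spacing_px, nrmse) and `argmin`
#'   (topology, best_spacing_px)
#' @export
sweep_modulation_size <- function(geometry, sizes_px = c(2, 3, 4, 6, 8, 12, 20),
                                  topologies = c("random", "hexagonal",
                                                 "regular", "spiral"),
                                  field_px = c(256L, 256L), K = 10L, os = 4L,
                                  seed = 1L, target_visibility = 0.15,
                                  sample_shape = "julia") {
  if (any(sizes_px < 2)) stop("spacings below 2 px cannot be resolved")
  h <- calibrated_cone_height(geometry, spacing_px = 4, os = os,
                              target = target_visibility)
  grid <- sample_grid(geometry, field_px, os = os)
  sample <- study_phantom(sample_shape, grid, geometry)
  D0 <- theoretical_displacement(sample, geometry, os = os)
  rows <- list()
  for (topo in topologies) {
    for (s in sizes_px) {
      r <- run_retrieval(topo, sample, geometry, spacing_px = s,
                         cone_height_um = h, K = K, shift_axes = "xy",
                         field_px = field_px, os = os,
                         seed = derive_seed(seed, match(topo, topologies) * 100 +
                                              match(s, sizes_px)))
      rows[[length(rows) + 1L]] <- data.frame(
        topology = topo, spacing_px = s,
        nrmse = nrmse(r$retrieval$D_y, D0$D0_y))
    }
  }
  tab <- do.call(rbind, rows)
  argmin <- do.call(rbind, lapply(split(tab, tab$topology), function(d)
    data.frame(topology = d$topology[1],
               best_spacing_px = d$spacing_px[which.min(d$nrmse)])))
  rownames(argmin) <- NULL
  list(table = tab, argmin = argmin)
}

#' Topology comparison across phantoms
#'
#' All image-quality indices on the retrieved vertical displacement of each
#' phantom under each mask topology, single-axis shifts.
#'
#' @inheritParams sweep_modulation_size
#' @param samples phantom shape tags
#' @param spacing_px design spacing (px)
#' @param metrics which indices to compute
#' @return data.frame (sample, topology, metric, value)
#' @export
compare_masks <- function(geometry,
                          samples = c("wire", "sphere", "cube", "torus",
                                      "shepp_logan", "julia"),
                          topologies = c("random", "hexagonal", "regular",
                                         "spiral"),
                          spacing_px = 4, field_px = c(256L, 256L), K = 10L,
                          os = 4L, seed = 1L, target_visibility = 0.15,
                          metrics = c("nrmse", "ssim", "ms_ssim", "sr_sim",
                                      "vsi")) {
  h <- calibrated_cone_height(geometry, spacing_px = spacing_px, os = os,
                              target = target_visibility)
  grid <- sample_grid(geometry, field_px, os = os)
  rows <- list()
  for (sh in samples) {
    sample <- study_phantom(sh, grid, geometry)
    D0 <- theoretical_displacement(sample, geometry, os = os)
    for (topo in topologies) {
      r <- run_retrieval(topo, sample, geometry, spacing_px = spacing_px,
                         cone_height_um = h, K = K, shift_axes = "x",
                         field_px = field_px, os = os,
                         seed = derive_seed(seed, match(sh, samples) * 1000 +
                                              match(topo, topologies)))
      Dy <- r$retrieval$D_y
      for (m in metrics) {
        v <- switch(m,
          nrmse = nrmse(Dy, D0$D0_y),
          ssim = ssim(Dy, D0$D0_y),
          ms_ssim = ms_ssim(Dy, D0$D0_y),
          sr_sim = sr_sim(Dy, D0$D0_y),
          vsi = vsi(Dy, D0$D0_y))
        rows[[length(rows) + 1L]] <- data.frame(sample = sh, topology = topo,
                                                metric = m, value = v)
      }
    }
  }
  do.call(rbind, rows)
}

#' FRC resolution experiment
#'
#' Two independent realizations (fresh mask randomness, shifts and noise) of
#' the fractal retrieval per topology; Fourier ring correlation between the
#' two vertical displacement maps, resolution at the 1/7 crossing.
#'
#' @inheritParams sweep_modulation_size
#' @param spacing_px design spacing
#' @param sample_shape phantom (fractal)
#' @return list with `table` (topology, resolution_px, crossed) and `curves`
#'   (per-topology data.frame of frequency vs correlation)
#' @export
frc_experiment <- function(geometry, topologies = c("random", "hexagonal",
                                                    "spiral"),
                           spacing_px = 4, field_px = c(512L, 512L), K = 10L,
                           os = 4L, seed = 1L, target_visibility = 0.15,
                           sample_shape = "julia") {
  h <- calibrated_cone_height(geometry, spacing_px = spacing_px, os = os,
                              target = target_visibility)
  grid <- sample_grid(geometry, field_px, os = os)
  sample <- study_phantom(sample_shape, grid, geometry)
  curves <- list(); rows <- list()
  for (topo in topologies) {
    Dy <- lapply(1:2, function(rep) {
      r <- run_retrieval(topo, sample, geometry, spacing_px = spacing_px,
                         cone_height_um = h, K = K, shift_axes = "x",
                         field_px = field_px, os = os,
                         seed = derive_seed(seed, match(topo, topologies) * 10 + rep))
      r$retrieval$D_y
    })
    f <- frc(Dy[[1]], Dy[[2]])
    rows[[length(rows) + 1L]] <- data.frame(topology = topo,
                                            resolution_px = f$resolution_px,
                                            crossed = f$crossed)
    curves[[topo]] <- data.frame(topology = topo, frequency = f$frequencies,
                                 correlation = f$correlation)
  }
  list(table = do.call(rbind, rows), curves = do.call(rbind, curves))
}

#' Angular-sensitivity table
#'
#' Shepp-Logan phantom, single-axis shifts; the standard deviation of the
#' retrieved vertical refraction angle in eight 5 x 40 px windows auto-placed
#' in the sample-free border zone, per topology, in nanoradians.
#'
#' @inheritParams sweep_modulation_size
#' @param spacing_px design spacing
#' @param n_windows number of windows
#' @param win window size `c(rows, cols)`
#' @return data.frame (topology, mean_nrad, se_nrad)
#' @export
sensitivity_table <- function(geometry, topologies = c("random", "hexagonal",
                                                       "spiral"),
                              spacing_px = 4, field_px = c(256L, 320L),
                              K = 10L, os = 4L, seed = 1L,
                              target_visibility = 0.15, n_windows = 8L,
                              win = c(5L, 40L)) {
  h <- calibrated_cone_height(geometry, spacing_px = spacing_px, os = os,
                              target = target_visibility)
  grid <- sample_grid(geometry, field_px, os = os)
  sample <- study_phantom("shepp_logan", grid, geometry)
  support <- phantom_support(sample, os = os)
  windows <- place_windows(support, n = n_windows, win = win)
  rows <- list()
  for (topo in topologies) {
    r <- run_retrieval(topo, sample, geometry, spacing_px = spacing_px,
                       cone_height_um = h, K = K, shift_axes = "x",
                       field_px = field_px, os = os,
                       seed = derive_seed(seed, match(topo, topologies) * 7L))
    a <- angular_sensitivity(r$retrieval$D_y, geometry, windows,
                             support = support)
    rows[[length(rows) + 1L]] <- data.frame(topology = topo,
                                            mean_nrad = a$mean_nrad,
                                            se_nrad = a$se_nrad)
  }
  do.call(rbind, rows)
}

#' Synthetic fiber phantom for dark-field experiments
#'
#' Two anisotropically scattering fiber bundles (orthogonal orientations) and
#' a non-scattering nylon wire, as a stand-in preset for the measured
#' dark-field scene; labelled synthetic because the study's dark-field data
#' are experimental only.
#'
#' @param grid a [sample_grid()]
#' @param sigma_px scattering blur sigma inside the bundles (detector px)
#' @export
fiber_phantom <- function(grid, sigma_px = 1.0) {
  co <- grid_coords_mm(grid)
  X <- matrix(co$x, grid$nr, grid$nc, byrow = TRUE)
  Y <- matrix(co$y, grid$nr, grid$nc)
  w <- (grid$nc * grid$pitch_um / 1000) / 2
  hgt <- (grid$nr * grid$pitch_um / 1000) / 2
  # thin nylon wire (vertical) plus two rectangular bundles
  t <- 2 * sqrt(pmax(0.4^2 - (X + 0.5 * w)^2, 0))
  bundle_h <- abs(Y - 0.35 * hgt) < 0.18 * hgt & abs(X) < 0.55 * w
  bundle_v <- abs(Y + 0.35 * hgt) < 0.18 * hgt & abs(X) < 0.55 * w
  t <- t + 0.8 * (bundle_h | bundle_v)
  sx <- matrix(0, grid$nr, grid$nc); sy <- matrix(0, grid$nr, grid$nc)
  sx[bundle_h] <- sigma_px   # fibers along y scatter across x
  sy[bundle_v] <- sigma_px
  s <- new_thickness_map(t, "nylon", grid$pitch_um, "fiber_synthetic")
  set_darkfield_kernel(s, list(sx = sx, sy = sy))
}
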