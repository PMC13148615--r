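## Forward simulation: from mask + phantom + geometry to noisy detector
## reference/sample image pairs.
##
## Everything is computed on an oversampled detector-conjugate grid (`os`
## cells per detector pixel and axis). The mask raster is generated over an
## extended field (detector field + margin on every side) so that membrane
## shifts of up to `margin_px` pixels crop different windows of the same
## physical membrane, exactly as moving the real membrane does.

#' Complex transmission screen from a thickness map
#'
#' Projection approximation: intensity transmission exp(-mu t) and phase
#' -(2 pi / lambda) delta t. Accepts a phantom (`mobi_thickness`, mm) or a
#' mask (`mobi_mask`, um).
#'
#' @param t a `mobi_thickness` or `mobi_mask`
#' @param geometry an [acquisition_geometry()] (supplies the wavelength)
#' @return list with `transmission` (intensity factor) and `phase` (radians)
#' @export
screen_from_thickness <- function(t, geometry) {
  mc <- material_constants(t$material)
  t_m <- if (inherits(t, "mobi_mask")) t$thickness * 1e-6 else t$thickness * 1e-3
  list(transmission = exp(-mc$mu_per_m * t_m),
       phase = -(2 * pi / geometry$wavelength) * mc$delta * t_m)
}

#' Build a mask sized for a detector field at a given modulation spacing
#'
#' Converts a design peak-to-peak spacing in detector pixels into
#' membrane-plane micrometres via the membrane magnification, generates the
#' topology's point set over the detector field plus shift margin, and
#' rasterizes it on the oversampled detector-conjugate grid.
#'
#' Spacing conventions per topology: lattice pitch (hexagonal, regular),
#' density-matched Vogel scale `c = s/sqrt(pi)` (so modulations per area equal
#' the square grid's `1/s^2`), and the same nominal density for the random
#' pattern (`n = area/s^2`) with a hard core of `0.3 s` so grains may clump
#' as on sandpaper. Modulator diameter defaults to the spacing itself
#' (uniform in `[0.5 s, 1.5 s]` for the random topology).
#'
#' @param topology one of "random", "hexagonal", "regular", "spiral"
#' @param spacing_px design peak-to-peak modulation distance, detector pixels
#' @param geometry an [acquisition_geometry()]
#' @param field_px detector field `c(rows, cols)` to cover
#' @param margin_px extra border (detector px) on each side for shifts
#' @param os oversampling factor
#' @param profile modulator profile; default SiO2 cone of nominal height
#'   `cone_height_um` (calibrate with [calibrate_mask_visibility()])
#' @param cone_height_um nominal cone height before calibration (um)
#' @param seed RNG seed (random topology only)
#' @return a `mobi_mask` whose raster covers `(field + 2 margin) * os` cells
#' @export
build_mask <- function(topology, spacing_px, geometry, field_px,
                       margin_px = 160L, os = 4L, profile = NULL,
                       cone_height_um = 20, seed = 1L) {
  stopifnot(spacing_px > 0)
  px_mem <- plane_pitch_um(geometry, geometry$d_source_membrane)  # um/detector px
  ext_px <- field_px + 2L * margin_px
  extent <- c(ext_px[2], ext_px[1]) * px_mem       # (width, height) um
  # fabricated dimensions are whole micrometres at the membrane plane; the
  # design pitch is therefore generically incommensurate with the projected
  # detector pixel (an exactly pixel-commensurate lattice would alias with
  # the integer-pixel shift protocol in a way no physical mask does)
  s_um <- max(1, round(spacing_px * px_mem))
  # modulators are discrete dots: diameter 0.7 of the spacing, the ratio of
  # the drilled masks (60 um holes at the few-pixel design spacing)
  d_um <- max(1, round(0.7 * s_um))
  if (is.null(profile)) profile <- list(type = "cone", height = cone_height_um)
  pts <- switch(topology,
    regular = gen_square_points(s_um, extent, diameter = d_um),
    hexagonal = gen_hexagonal_points(s_um, extent, diameter = d_um),
    spiral = {
      c_um <- s_um / sqrt(pi)
      # enough points for the spiral to cover the field corner-to-corner
      n <- ceiling(1.05 * (extent[1]^2 + extent[2]^2) / 4 / c_um^2)
      gen_vogel_spiral_points(n, c_um, extent, diameter = d_um)
    },
    random = {
      # sandpaper-like: a single layer of grains, side by side — the hard
      # core keeps grains from stacking while leaving the paving uneven;
      # graded-grit size spread of +/- 20% around the design diameter.
      # The design spacing of the random topology is its mean
      # nearest-neighbour distance: solve the hard-core (Matern-like)
      # mean-NN relation for the point density.
      lam <- random_density_for_spacing(s_um, 0.6 * s_um)
      n <- max(1L, round(extent[1] * extent[2] * lam))
      gen_random_points(n, extent, min_separation = 0.6 * s_um,
                        diameters = c(0.8, 1.2) * d_um, diameter_range = TRUE,
                        seed = seed)
    },
    stop("unknown topology '", topology, "'")
  )
  grid_pitch <- px_mem / os
  rasterize_mask(pts, profile, material = if (profile$type == "hole") "ni" else "sio2",
                 grid_pitch = grid_pitch)
}

## density lambda (points per um^2) of a hard-core uniform process whose
## mean nearest-neighbour distance equals `target`: for core radius r_c,
## E[NN] = r_c + exp(lam pi r_c^2) * erfc(r_c sqrt(pi lam)) / (2 sqrt(lam))
random_density_for_spacing <- function(target, r_c) {
  erfc <- function(x) 2 * stats::pnorm(-sqrt(2) * x)
  enn <- function(lam) r_c + exp(lam * pi * r_c^2) *
    erfc(r_c * sqrt(pi * lam)) / (2 * sqrt(lam))
  stats::uniroot(function(l) enn(l) - target,
                 lower = 1e-8 / target^2, upper = 3 / target^2,
                 tol = 1e-12)$root
}

#' Noise-free reference intensity over the full extended mask raster
#'
#' Mask transmission times mean counts, blurred by the projected source spot
#' (the blur that turns sharp modulator rims into the smooth intensity
#' modulations seen on the detector).
#'
#' @param mask a `mobi_mask` (extended raster, os grid)
#' @param geometry an [acquisition_geometry()]
#' @param os oversampling factor of the mask raster
#' @param source_blur apply the source-spot Gaussian blur (default TRUE)
#' @return matrix of expected counts on the oversampled extended grid
#' @export
reference_intensity <- function(mask, geometry, os = 4L, source_blur = TRUE) {
  scr <- screen_from_thickness(mask, geometry)
  I <- scr$transmission
  if (source_blur) {
    sig <- source_blur_sigma_px(geometry, geometry$d_source_membrane) * os
    if (sig > 0) I <- gaussian_blur(I, sig)
  }
  # the count level is defined on the detector, i.e. after the mask
  I * (geometry$mean_counts / mean(I))
}

#' Calibrate the cone height of a mask to a target reference visibility
#'
#' The modulation amplitude (cone height) is set so that the noise-free
#' reference image has a chosen visibility std/mean on the detector grid.
#' Monotone in the height, solved by bisection on a log scale. Hole-profile
#' masks are returned unchanged (their depth is the physical plate).
#'
#' @param mask a cone-profile `mobi_mask`
#' @param geometry an [acquisition_geometry()]
#' @param os oversampling factor of the mask raster
#' @param target visibility std/mean of the noise-free reference
#' @return the mask with rescaled thickness, with attribute `visibility`
#' @export
calibrate_mask_visibility <- function(mask, geometry, os = 4L, target = 0.15) {
  if (identical(mask$profile$type, "hole")) return(mask)
  vis_at <- function(logf) {
    m <- scale_mask_height(mask, exp(logf))
    I <- bin_image(reference_intensity(m, geometry, os = os), os)
    stats::sd(I) / mean(I)
  }
  f <- tryCatch(
    stats::uniroot(function(lf) vis_at(lf) - target, lower = log(1e-3),
                   upper = log(1e3), tol = 1e-3)$root,
    error = function(e) stop("visibility ", target, " unreachable for this mask: ",
                             conditionMessage(e))
  )
  out <- scale_mask_height(mask, exp(f))
  attr(out, "visibility") <- vis_at(f)
  out
}

## displacement field (detector px) and transmission of a phantom on its grid
sample_optics <- function(sample, geometry) {
  mc <- material_constants(sample$material)
  scr <- screen_from_thickness(sample, geometry)
  g <- image_gradient(sample$thickness * 1e-3)      # m per cell
  ds <- sample$pitch_um * 1e-6                      # cell size, m
  alpha_x <- mc$delta * g$dx / ds
  alpha_y <- mc$delta * g$dy / ds
  f <- geometry$d_sample_detector / (geometry$pixel_size * 1e-6)
  list(transmission = scr$transmission,
       dx_px = f * alpha_x, dy_px = f * alpha_y)
}

# spatially varying Gaussian blur by blending a small set of blur levels
varying_blur <- function(img, sigma_map) {
  sig <- unique(round(as.vector(sigma_map), 2))
  sig <- sort(sig)
  if (length(sig) == 1L) {
    return(if (sig <= 0) img else gaussian_blur(img, sig))
  }
  if (length(sig) > 6L) {  # quantize to keep the number of FFTs bounded
    sig <- seq(min(sig), max(sig), length.out = 6L)
  }
  blurred <- lapply(sig, function(s) if (s <= 0) img else gaussian_blur(img, s))
  idx <- findInterval(sigma_map, sig, all.inside = TRUE)
  lo <- sig[idx]; hi <- sig[pmin(idx + 1L, length(sig))]
  w <- ifelse(hi > lo, (sigma_map - lo) / (hi - lo), 0)
  out <- img
  for (j in seq_along(sig)) {
    sel_lo <- idx == j
    if (any(sel_lo)) out[sel_lo] <- (1 - w[sel_lo]) * blurred[[j]][sel_lo] +
        w[sel_lo] * blurred[[min(j + 1L, length(sig))]][sel_lo]
  }
  out
}

#' Single detector image under the warp or Fresnel forward model
#'
#' warp: the (pre-blurred) reference pattern is resampled by the sample's
#' refraction displacement field, multiplied by the sample transmission and
#' optionally blurred by the phantom's dark-field kernel. fresnel: the complex
#' product of mask and sample screens is free-space propagated over the
#' cone-beam effective distance `z2 / M_sample`, squared, and source-blurred.
#' Both end with pixel integration and (optionally) Poisson noise.
#'
#' @param ref_os oversampled noise-free reference intensity (field crop), from
#'   [reference_intensity()]; for the fresnel model pass the mask instead via
#'   `mask_screen`
#' @param sample_opt optics from the phantom (internal `sample_optics()`
#'   output on the same grid), or NULL for a reference image
#' @param geometry an [acquisition_geometry()]
#' @param os oversampling factor
#' @param df_sigma_os optional dark-field blur map (os-grid sigma, os cells)
#' @param noise add Poisson noise
#' @param seed RNG seed used when `noise`
#' @return detector-resolution image in counts
#' @export
forward_image <- function(ref_os, sample_opt = NULL, geometry, os = 4L,
                          df_sigma_os = NULL, noise = TRUE, seed = 1L) {
  I <- ref_os
  if (!is.null(sample_opt)) {
    if (!is.null(df_sigma_os)) I <- varying_blur(I, df_sigma_os)
    I <- warp_image(I, sample_opt$dx_px * os, sample_opt$dy_px * os)
    I <- I * sample_opt$transmission
  }
  I_det <- bin_image(I, os)
  if (noise) {
    set.seed(seed)
    I_det <- matrix(stats::rpois(length(I_det), pmax(I_det, 0)),
                    nrow(I_det), ncol(I_det))
  }
  I_det
}

#' Acquire a series of reference/sample image pairs
#'
#' For each of the K pairs the membrane is shifted by an integer number of
#' detector pixels drawn uniformly from `shift_range` (random sign) along the
#' active axes, then one reference and one sample image are formed with
#' independent Poisson noise. Deterministic for a fixed seed.
#'
#' @param mask extended-raster `mobi_mask` from [build_mask()]
#' @param sample `mobi_thickness` on the os sample grid of `field_px`, or NULL
#'   for reference-only series
#' @param geometry an [acquisition_geometry()]
#' @param K number of pairs
#' @param shift_axes "x" or "xy"
#' @param shift_range `c(min, max)` shift magnitude, detector pixels
#' @param seed master seed; per-pair noise seeds derive from it
#' @param os oversampling factor (must match the mask raster)
#' @param field_px detector field `c(rows, cols)`
#' @param noise add Poisson noise
#' @return object of class `mobi_pairs`: lists `Ir`, `Is` of K detector
#'   images, `shifts` (K x 2, px), plus geometry and bookkeeping
#' @export
acquire_series <- function(mask, sample, geometry, K = 10L,
                           shift_axes = c("x", "xy"), shift_range = c(50L, 150L),
                           seed = 1L, os = 4L, field_px = c(256L, 256L),
                           noise = TRUE) {
  shift_axes <- match.arg(shift_axes)
  stopifnot(K >= 1)
  ref_full <- reference_intensity(mask, geometry, os = os)
  nr_full <- nrow(ref_full); nc_full <- ncol(ref_full)
  margin_r <- (nr_full / os - field_px[1]) %/% 2
  margin_c <- (nc_full / os - field_px[2]) %/% 2
  if (max(shift_range) > min(margin_r, margin_c)) {
    stop("mask margin (", min(margin_r, margin_c),
         " px) smaller than the maximum shift ", max(shift_range), " px")
  }
  sample_opt <- if (!is.null(sample)) sample_optics(sample, geometry) else NULL
  df_sigma_os <- NULL
  if (!is.null(sample) && !is.null(sample$df_sigma_px)) {
    s <- sample$df_sigma_px
    if (is.list(s)) s <- s$sx  # isotropic path; anisotropic handled separately
    if (length(s) == 1L) s <- matrix(s, field_px[1] * os, field_px[2] * os)
    df_sigma_os <- s * os
  }
  aniso <- !is.null(sample) && is.list(sample$df_sigma_px)
  set.seed(seed)
  draw_shift <- function() {
    mag <- if (shift_range[2] > shift_range[1])
      sample.int(shift_range[2] - shift_range[1] + 1L, 1L) + shift_range[1] - 1L
    else shift_range[1]
    if (mag == 0L) 0L else mag * sample(c(-1L, 1L), 1L)
  }
  shifts <- matrix(0L, K, 2L)
  for (k in seq_len(K)) {
    shifts[k, 1] <- draw_shift()
    if (shift_axes == "xy") shifts[k, 2] <- draw_shift()
  }
  Ir <- vector("list", K); Is <- vector("list", K)
  for (k in seq_len(K)) {
    r0 <- (margin_r + shifts[k, 2]) * os
    c0 <- (margin_c + shifts[k, 1]) * os
    crop <- ref_full[r0 + seq_len(field_px[1] * os),
                     c0 + seq_len(field_px[2] * os)]
    Ir[[k]] <- forward_image(crop, NULL, geometry, os = os, noise = noise,
                             seed = derive_seed(seed, 2L * k))
    if (!is.null(sample)) {
      I <- crop
      if (aniso) {
        I <- anisotropic_blur(I, sample$df_sigma_px$sx * os,
                              sample$df_sigma_px$sy * os)
      } else if (!is.null(df_sigma_os)) {
        I <- varying_blur(I, df_sigma_os)
      }
      I <- warp_image(I, sample_opt$dx_px * os, sample_opt$dy_px * os)
      I <- I * sample_opt$transmission
      I_det <- bin_image(I, os)
      if (noise) {
        set.seed(derive_seed(seed, 2L * k + 1L))
        I_det <- matrix(stats::rpois(length(I_det), pmax(I_det, 0)),
                        nrow(I_det), ncol(I_det))
      }
      Is[[k]] <- I_det
    } else {
      Is[[k]] <- Ir[[k]]
    }
  }
  p <- list(Ir = Ir, Is = Is, shifts = shifts, geometry = geometry,
            seed = seed, os = os, field_px = as.integer(field_px),
            topology = mask$topology_tag)
  class(p) <- "mobi_pairs"
  p
}

# anisotropic Gaussian blur with (possibly spatially varying) axis sigmas;
# maps with distinct regions are blended per unique (sx, sy) combination
anisotropic_blur <- function(img, sx, sy) {
  if (length(sx) == 1L && length(sy) == 1L) return(gaussian_blur(img, c(sy, sx)))
  key <- paste(round(sx, 2), round(sy, 2))
  out <- img
  for (k in unique(as.vector(key))) {
    sel <- key == k
    s <- as.numeric(strsplit(k, " ")[[1]])
    if (any(s > 0)) {
      b <- gaussian_blur(img, c(s[2], s[1]))
      out[sel] <- b[sel]
    }
  }
  out
}

#' @export
print.mobi_pairs <- function(x, ...) {
  cat(sprintf("<mobi_pairs> K = %d pairs of %d x %d px (%s mask), shifts x:[%d,%d] y:[%d,%d]\n",
              length(x$Ir), x$field_px[1], x$field_px[2],
              x$topology %||% "?", min(x$shifts[, 1]), max(x$shifts[, 1]),
              min(x$shifts[, 2]), max(x$shifts[, 2])))
  invisible(x)
}

#' Angular-spectrum Fresnel propagation of a complex field
#'
#' @param U complex matrix (field), sampled at `pitch_m` metres
#' @param dist_m propagation distance (m)
#' @param wavelength metres
#' @param pitch_m sample pitch (m)
#' @return propagated complex field
#' @export
fresnel_propagate <- function(U, dist_m, wavelength, pitch_m) {
  fy <- fft_freq(nrow(U)) / pitch_m
  fx <- fft_freq(ncol(U)) / pitch_m
  # carrier convention exp(-ikz): a positive-delta screen (phase -k delta t)
  # then refracts toward thinner material, matching the ray model
  H <- exp(+1i * pi * wavelength * dist_m * outer(fy^2, fx^2, "+"))
  stats::fft(stats::fft(U) * H, inverse = TRUE) / length(U)
}

#' Fresnel-model detector image
#'
#' Wave-optical cross-check of the warp model: the mask (and optionally the
#' sample) screens multiply a unit plane wave on the oversampled grid, the
#' product propagates over the cone-beam effective distance `z2 / M_sample`,
#' and the intensity is source-blurred, pixel-integrated and Poisson-sampled.
#'
#' @param mask_crop `mobi_mask`-style thickness crop (um matrix) of field size
#' @param mask_material material of the mask
#' @param sample optional `mobi_thickness` on the same grid
#' @param geometry an [acquisition_geometry()]
#' @param os oversampling factor
#' @param noise,seed Poisson noise controls
#' @export
fresnel_image <- function(mask_crop, mask_material, sample = NULL, geometry,
                          os = 4L, noise = FALSE, seed = 1L) {
  mc <- material_constants(mask_material)
  t_m <- mask_crop * 1e-6
  U <- exp(-mc$mu_per_m * t_m / 2) *
    exp(1i * (-(2 * pi / geometry$wavelength) * mc$delta * t_m))
  if (!is.null(sample)) {
    scr <- screen_from_thickness(sample, geometry)
    U <- U * sqrt(scr$transmission) * exp(1i * scr$phase)
  }
  z_eff <- geometry$d_sample_detector / geometry$mag_sample
  pitch_m <- plane_pitch_um(geometry, geometry$d_source_sample) * 1e-6 / os
  Up <- fresnel_propagate(U, z_eff, geometry$wavelength, pitch_m)
  I <- Mod(Up)^2 * geometry$mean_counts
  sig <- source_blur_sigma_px(geometry, geometry$d_source_membrane) * os
  if (sig > 0) I <- gaussian_blur(I, sig)
  I_det <- bin_image(I, os)
  if (noise) {
    set.seed(seed)
    I_det <- matrix(stats::rpois(length(I_det), pmax(I_det, 0)),
                    nrow(I_det), ncol(I_det))
  }
  I_det
}

#' Persist / load an image-pair series as TIFF frames + JSON manifest
#'
#' Frames are written as 32-bit float TIFFs (counts divided by a stored
#' scale), one file per frame, with a `manifest.json` recording shifts,
#' geometry and seed. `read_pairs()` also ingests externally measured stacks
#' that follow the same manifest layout.
#'
#' @param pairs a `mobi_pairs`
#' @param dir output directory (created)
#' @export
write_pairs <- function(pairs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  K <- length(pairs$Ir)
  scale <- max(unlist(lapply(pairs$Ir, max)), unlist(lapply(pairs$Is, max)), 1)
  for (k in seq_len(K)) {
    tiff::writeTIFF(pairs$Ir[[k]] / scale, file.path(dir, sprintf("ref_%03d.tif", k)),
                    bits.per.sample = 32L)
    tiff::writeTIFF(pairs$Is[[k]] / scale, file.path(dir, sprintf("sam_%03d.tif", k)),
                    bits.per.sample = 32L)
  }
  man <- list(K = K, scale = scale, shifts = pairs$shifts, seed = pairs$seed,
              field_px = pairs$field_px, topology = pairs$topology,
              geometry = unclass(pairs$geometry)[c(
                "d_source_membrane", "d_source_sample", "d_sample_detector",
                "pixel_size", "energy_kev", "source_fwhm", "mean_counts")])
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  g <- do.call(acquisition_geometry, as.list(man$geometry))
  K <- man$K
  Ir <- lapply(seq_len(K), function(k)
    tiff::readTIFF(file.path(dir, sprintf("ref_%03d.tif", k))) * man$scale)
  Is <- lapply(seq_len(K), function(k)
    tiff::readTIFF(file.path(dir, sprintf("sam_%03d.tif", k))) * man$scale)
  p <- list(Ir = Ir, Is = Is, shifts = matrix(unlist(man$shifts), K, 2),
            geometry = g, seed = man$seed, field_px = man$field_px,
            topology = man$topology)
  class(p) <- "mobi_pairs"
  p
}
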