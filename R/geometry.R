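## Acquisition geometry and X-ray optical constants.

#' Optical constants table (8.6 keV)
#'
#' Refractive-index decrement delta and linear attenuation mu for the materials
#' used in the study, at the 8.6 keV mean energy of a Cu-anode source. delta is
#' computed from the classical-electron-radius formula
#' delta = r_e lambda^2 n_e / (2 pi); mu from NIST-style elemental mass
#' attenuation coefficients combined by mass fraction. Versioned in-code so
#' runs are reproducible offline; values are for the projection approximation
#' only, anomalous dispersion near the Ni K edge is not modelled.
#'
#' @format list keyed by material, each with `delta` (dimensionless),
#'   `mu_per_m` (1/m), `density` (g/cm^3)
#' @export
optical_constants <- list(
  # nylon PA6 (C6H11NO)n, rho 1.14
  nylon = list(delta = 3.51e-06, mu_per_m = 508, density = 1.14),
  # fused silica, rho 2.20
  sio2 = list(delta = 6.17e-06, mu_per_m = 6540, density = 2.20),
  # nickel, rho 8.91 (8.6 keV is just above the K edge at 8.33 keV)
  ni = list(delta = 2.39e-05, mu_per_m = 249000, density = 8.91),
  # 3D-printing resin (acrylate, approximated by PMMA-like composition)
  resin = list(delta = 3.63e-06, mu_per_m = 720, density = 1.18)
)

#' Look up optical constants for a material at 8.6 keV
#' @param material one of `names(optical_constants)`
#' @return list with `delta` and `mu_per_m`
#' @export
material_constants <- function(material) {
  m <- optical_constants[[tolower(material)]]
  if (is.null(m)) {
    stop("no optical constants for material '", material, "'; known: ",
         paste(names(optical_constants), collapse = ", "))
  }
  m
}

#' Cone-beam acquisition geometry
#'
#' Distances follow the Xeuss-like laboratory layout: source, then membrane,
#' then sample, then detector, all on one axis. Plane magnifications are the
#' ratio of total source-detector distance to source-plane distance.
#'
#' @param d_source_membrane source-to-membrane distance (m)
#' @param d_source_sample source-to-sample distance (m)
#' @param d_sample_detector sample-to-detector distance z2 (m)
#' @param pixel_size detector pixel pitch (um)
#' @param detector_shape integer `c(rows, cols)`
#' @param energy_kev photon energy (keV)
#' @param source_fwhm source spot FWHM (um)
#' @param mean_counts mean photons per detector pixel in the flat field
#' @return object of class `mobi_geometry`
#' @export
acquisition_geometry <- function(d_source_membrane = 0.33,
                                 d_source_sample = 0.55,
                                 d_sample_detector = 0.80,
                                 pixel_size = 75,
                                 detector_shape = c(514L, 1030L),
                                 energy_kev = 8.6,
                                 source_fwhm = 50,
                                 mean_counts = 75000) {
  stopifnot(d_source_membrane > 0, d_source_sample > d_source_membrane,
            d_sample_detector > 0, pixel_size > 0, mean_counts > 0)
  d_tot <- d_source_sample + d_sample_detector
  g <- list(
    d_source_membrane = d_source_membrane,
    d_source_sample = d_source_sample,
    d_sample_detector = d_sample_detector,
    d_total = d_tot,
    pixel_size = pixel_size,
    detector_shape = as.integer(detector_shape),
    energy_kev = energy_kev,
    source_fwhm = source_fwhm,
    mean_counts = mean_counts,
    mag_membrane = d_tot / d_source_membrane,
    mag_sample = d_tot / d_source_sample,
    wavelength = 1.23984193e-09 / energy_kev  # m
  )
  class(g) <- "mobi_geometry"
  g
}

#' @export
print.mobi_geometry <- function(x, ...) {
  cat("<mobi_geometry>\n")
  cat(sprintf("  source-membrane %.3g m  source-sample %.3g m  z2 %.3g m\n",
              x$d_source_membrane, x$d_source_sample, x$d_sample_detector))
  cat(sprintf("  detector %d x %d px of %.3g um, %.3g keV, %g counts/px\n",
              x$detector_shape[1], x$detector_shape[2], x$pixel_size,
              x$energy_kev, x$mean_counts))
  cat(sprintf("  M_membrane %.4g  M_sample %.4g\n", x$mag_membrane, x$mag_sample))
  invisible(x)
}

#' Magnification of an arbitrary plane
#' @param geometry a [acquisition_geometry()] object
#' @param d_source_plane source-to-plane distance (m)
#' @export
plane_magnification <- function(geometry, d_source_plane) {
  geometry$d_total / d_source_plane
}

#' Detector-plane source blur (pixels, standard deviation)
#'
#' Penumbral blur of a plane imaged by a finite Gaussian source spot:
#' FWHM at the detector = source_fwhm * (M_plane - 1).
#' @inheritParams plane_magnification
#' @export
source_blur_sigma_px <- function(geometry, d_source_plane = geometry$d_source_membrane) {
  M <- plane_magnification(geometry, d_source_plane)
  fwhm_um <- geometry$source_fwhm * (M - 1)
  fwhm_um / geometry$pixel_size / (2 * sqrt(2 * log(2)))
}

#' Pixel pitch of the detector grid referred back to a given plane (um)
#' @inheritParams plane_magnification
#' @export
plane_pitch_um <- function(geometry, d_source_plane) {
  geometry$pixel_size / plane_magnification(geometry, d_source_plane)
}

#' Convert displacement (detector px) to refraction angle (rad)
#'
#' alpha = D * pixel_size / z2; the inverse of the ray-optical displacement a
#' refracting sample imprints on the modulation pattern.
#' @param d_px displacement map or scalar, detector pixels
#' @param geometry a [acquisition_geometry()] object
#' @export
displacement_to_angle <- function(d_px, geometry) {
  d_px * (geometry$pixel_size * 1e-6) / geometry$d_sample_detector
}
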