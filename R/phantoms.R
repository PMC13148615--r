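## Parametric nylon phantoms as projected-thickness maps.
##
## A thickness map lives on a sample-plane grid conjugate to the detector:
## each cell is `pixel_size / M_sample` micrometres wide (divided by the
## oversampling factor when oversampled). Thickness is the material path
## length along the beam, in millimetres.

#' Sample-plane raster grid conjugate to the detector
#'
#' @param geometry an [acquisition_geometry()] object
#' @param field_px detector field `c(rows, cols)` covered by the grid
#' @param os integer oversampling factor (cells per detector pixel and axis)
#' @return list with `nr`, `nc`, `pitch_um` (sample-plane cell size), `os`
#' @export
sample_grid <- function(geometry, field_px, os = 1L) {
  pitch <- plane_pitch_um(geometry, geometry$d_source_sample) / os
  list(nr = as.integer(field_px[1] * os), nc = as.integer(field_px[2] * os),
       pitch_um = pitch, os = as.integer(os))
}

new_thickness_map <- function(thickness_mm, material, pitch_um, tag,
                              df_sigma_px = NULL) {
  stopifnot(all(is.finite(thickness_mm)), all(thickness_mm >= 0))
  t <- list(thickness = thickness_mm, material = material, pitch_um = pitch_um,
            tag = tag, df_sigma_px = df_sigma_px)
  class(t) <- "mobi_thickness"
  t
}

#' @export
print.mobi_thickness <- function(x, ...) {
  cat(sprintf("<mobi_thickness> %s (%s): %d x %d @ %.3g um, %.3g-%.3g mm\n",
              x$tag, x$material, nrow(x$thickness), ncol(x$thickness),
              x$pitch_um, min(x$thickness), max(x$thickness)))
  invisible(x)
}

# centered physical coordinates (mm) of a grid
grid_coords_mm <- function(grid) {
  px <- grid$pitch_um / 1000
  x <- (seq_len(grid$nc) - (grid$nc + 1) / 2) * px
  y <- (seq_len(grid$nr) - (grid$nr + 1) / 2) * px
  list(x = x, y = y)
}

# standard head-phantom ellipse table: x0, y0, a, b, angle(deg), intensity
shepp_logan_ellipses <- function() {
  rbind(
    c(0,      0,      0.69,   0.92,   0,  2.0),
    c(0, -0.0184,     0.6624, 0.874,  0, -0.98),
    c(0.22,   0,      0.11,   0.31, -18, -0.02),
    c(-0.22,  0,      0.16,   0.41,  18, -0.02),
    c(0,      0.35,   0.21,   0.25,   0,  0.01),
    c(0,      0.1,    0.046,  0.046,  0,  0.01),
    c(0,     -0.1,    0.046,  0.046,  0,  0.01),
    c(-0.08, -0.605,  0.046,  0.023,  0,  0.01),
    c(0,     -0.605,  0.023,  0.023,  0,  0.01),
    c(0.06,  -0.605,  0.023,  0.046,  0,  0.01)
  )
}

#' Projected thickness map of a parametric phantom
#'
#' Supported shapes, with the study's default dimensions:
#' \describe{
#'   \item{wire}{cylinder, diameter 1.5 mm; thickness = chord of the circle;
#'     axis horizontal by default (refraction purely vertical, in D_y)}
#'   \item{sphere}{ball, diameter 12 mm; thickness = chord}
#'   \item{cube}{side 7 mm; constant thickness over the square footprint}
#'   \item{torus}{outer diameter 13 mm, central hole diameter 3 mm, maximum
#'     thickness 3 mm; elliptical tube cross-section}
#'   \item{shepp_logan}{ellipse-stack head phantom over a 13 x 18 mm field,
#'     additive intensities rescaled to thickness 1-5 mm over the support}
#'   \item{julia}{smoothed escape-time map of z^2 + c, c = -0.8 + 0.156i, over
#'     an 18 x 10 mm window, scaled to a 5 mm maximum height}
#' }
#'
#' @param shape one of the tags above
#' @param grid a [sample_grid()]
#' @param material phantom material, default nylon
#' @param dims optional named list overriding the default dimensions (mm)
#' @param wire_axis "h" (horizontal axis, default; refraction then purely
#'   vertical, carried by D_y) or "v"
#' @param smooth_um edge-rounding scale (um, Gaussian sigma at the sample
#'   plane): finite fabrication resolution; 0 renders the pure geometry with
#'   cliff edges whose refraction exceeds any retrievable displacement
#' @return a `mobi_thickness` object
#' @export
phantom_thickness <- function(shape, grid, material = "nylon", dims = list(),
                              wire_axis = c("h", "v"), smooth_um = 0) {
  wire_axis <- match.arg(wire_axis)
  co <- grid_coords_mm(grid)
  X <- matrix(co$x, grid$nr, grid$nc, byrow = TRUE)
  Y <- matrix(co$y, grid$nr, grid$nc)
  t <- switch(shape,
    wire = {
      d <- dims$diameter %||% 1.5
      u <- if (wire_axis == "v") X else Y
      2 * sqrt(pmax((d / 2)^2 - u^2, 0))
    },
    sphere = {
      d <- dims$diameter %||% 12
      2 * sqrt(pmax((d / 2)^2 - X^2 - Y^2, 0))
    },
    cube = {
      s <- dims$side %||% 7
      s * (abs(X) <= s / 2) * (abs(Y) <= s / 2)
    },
    torus = {
      d_out <- dims$outer %||% 13; d_in <- dims$inner %||% 3
      tmax <- dims$max_thickness %||% 3
      rc <- (d_out + d_in) / 4          # tube center radius
      rt <- (d_out - d_in) / 4          # tube radius in the plane
      r <- sqrt(X^2 + Y^2)
      tmax * sqrt(pmax(1 - ((r - rc) / rt)^2, 0))
    },
    shepp_logan = {
      w <- dims$width %||% 13; h <- dims$height %||% 18
      tmin <- dims$t_min %||% 1; tmax <- dims$t_max %||% 5
      xn <- X / (w / 2); yn <- -Y / (h / 2)   # unit-square frame, y up
      acc <- matrix(0, grid$nr, grid$nc)
      for (i in seq_len(nrow(shepp_logan_ellipses()))) {
        e <- shepp_logan_ellipses()[i, ]
        ph <- e[5] * pi / 180
        xr <- (xn - e[1]) * cos(ph) + (yn - e[2]) * sin(ph)
        yr <- -(xn - e[1]) * sin(ph) + (yn - e[2]) * cos(ph)
        acc <- acc + e[6] * ((xr / e[3])^2 + (yr / e[4])^2 <= 1)
      }
      sup <- acc > 1e-9
      if (any(sup)) {
        lo <- min(acc[sup]); hi <- max(acc[sup])
        acc[sup] <- tmin + (tmax - tmin) * (acc[sup] - lo) / max(hi - lo, 1e-12)
        acc[!sup] <- 0
      }
      acc
    },
    julia = {
      w <- dims$width %||% 18; h <- dims$height %||% 10
      tmax <- dims$max_thickness %||% 5
      cc <- dims$c %||% complex(real = -0.8, imaginary = 0.156)
      maxit <- dims$maxit %||% 80
      # map the physical window onto the complex plane, 9 mm = 1 unit
      zx <- X / (w / 2) * 1.8; zy <- Y / (h / 2) * 1.0
      z <- complex(real = zx, imaginary = zy)
      esc <- matrix(maxit, grid$nr, grid$nc)
      alive <- matrix(TRUE, grid$nr, grid$nc)
      for (it in seq_len(maxit)) {
        z[alive] <- z[alive]^2 + cc
        gone <- alive & (Mod(z) > 4)
        # smoothed escape count for continuous thickness levels
        esc[gone] <- it - log2(pmax(log(Mod(z[gone])), 1e-12) / log(4))
        alive <- alive & !gone
      }
      esc <- esc - min(esc)
      tmax * esc / max(esc)
    },
    stop("unknown phantom shape '", shape, "'")
  )
  if (smooth_um > 0) t <- pmax(gaussian_blur(t, smooth_um / grid$pitch_um), 0)
  new_thickness_map(t, material, grid$pitch_um, shape)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Attach a dark-field (small-angle scattering) kernel to a phantom
#'
#' The warp forward model blurs the reference pattern locally with this
#' per-pixel Gaussian sigma (detector pixels). Real nylon phantoms scatter
#' negligibly; this is a synthetic feature for exercising dark-field
#' retrieval, not a reproduction of measured microstructure.
#'
#' @param sample a `mobi_thickness`
#' @param sigma_px matrix (same dim as the thickness map) or scalar; for the
#'   anisotropic variant pass a list `list(sx = , sy = )`
#' @export
set_darkfield_kernel <- function(sample, sigma_px) {
  sample$df_sigma_px <- sigma_px
  sample
}

#' Footprint (support) of a phantom on the detector grid
#' @param sample a `mobi_thickness` on a (possibly oversampled) grid
#' @param os oversampling of that grid relative to detector pixels
#' @return logical matrix at detector resolution, TRUE where the phantom sits
#' @export
phantom_support <- function(sample, os = 1L, rel_tol = 1e-2) {
  s <- sample$thickness > rel_tol * max(sample$thickness)
  if (os > 1L) s <- bin_image(s * 1, os) > 0
  s
}
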