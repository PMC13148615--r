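## Membrane (mask) topologies: point patterns and their physical rasterization.
##
## A membrane is a flat support carrying one modulator (SiO2 cone, or a hole in
## a Ni plate) per point of a planar pattern. Four topologies are supported:
## random (sandpaper-like), hexagonal (honeycomb), square grid, and the Vogel
## spiral r = c*sqrt(k), theta = k * golden angle, the sunflower pattern that
## packs the plane quasi-periodically with no preferred direction.

GOLDEN_ANGLE <- 2 * pi * (1 - 2 / (1 + sqrt(5)))  # 2*pi*(1 - 1/phi), ~2.39996 rad

new_point_set <- function(x, y, diameters, extent, topology_tag) {
  # zero-point sets are tolerated as a degenerate case (uniform plate)
  stopifnot(length(x) == length(y))
  if (length(diameters) == 1L) diameters <- rep(diameters, length(x))
  stopifnot(all(diameters > 0))
  ps <- list(x = x, y = y, diameters = diameters,
             extent = extent, topology_tag = topology_tag)
  class(ps) <- "mobi_point_set"
  ps
}

#' @export
print.mobi_point_set <- function(x, ...) {
  cat(sprintf("<mobi_point_set> %s: %d points over %.4g x %.4g um, d = %.3g-%.3g um\n",
              x$topology_tag, length(x$x), x$extent[1], x$extent[2],
              min(x$diameters), max(x$diameters)))
  invisible(x)
}

#' Random (sandpaper-like) point pattern by dart throwing
#'
#' Uniform points over the field with an optional hard-core minimum pairwise
#' separation, mimicking the grain distribution on sandpaper. Placement is
#' sequential rejection sampling on a neighbour grid; an over-dense request
#' fails rather than loops forever.
#'
#' @param n number of points
#' @param extent field size `c(width, height)` in membrane-plane micrometres
#' @param min_separation hard-core distance (um), 0 for pure binomial points
#' @param diameters per-point modulator diameters (um); scalar, vector, or
#'   range `c(d_min, d_max)` with `diameter_range = TRUE` draws uniform
#' @param diameter_range if TRUE, `diameters` is a `c(min, max)` uniform range
#' @param seed RNG seed (deterministic output for fixed seed)
#' @param max_tries placement attempts per point before giving up
#' @return a point set
#' @export
gen_random_points <- function(n, extent, min_separation = 0, diameters = 50,
                              diameter_range = FALSE, seed = 1L,
                              max_tries = 200L) {
  stopifnot(n >= 1, min_separation >= 0)
  set.seed(seed)
  w <- extent[1]; h <- extent[2]
  if (n >= 2 && min_separation > sqrt(w^2 + h^2)) {
    stop("min_separation ", min_separation,
         " um exceeds the field diagonal; cannot place ", n, " points")
  }
  xs <- numeric(n); ys <- numeric(n)
  if (min_separation <= 0) {
    xs <- stats::runif(n, 0, w); ys <- stats::runif(n, 0, h)
  } else {
    # hash occupied points on a grid of cell = min_separation for O(1) checks
    cell <- min_separation
    nx <- max(1L, ceiling(w / cell)); ny <- max(1L, ceiling(h / cell))
    grid <- vector("list", nx * ny)
    cell_id <- function(x, y) {
      ix <- pmin(pmax(floor(x / cell), 0), nx - 1)
      iy <- pmin(pmax(floor(y / cell), 0), ny - 1)
      as.integer(iy * nx + ix + 1)
    }
    placed <- 0L
    while (placed < n) {
      ok <- FALSE
      for (t in seq_len(max_tries)) {
        px <- stats::runif(1, 0, w); py <- stats::runif(1, 0, h)
        ix <- (px %/% cell); iy <- (py %/% cell)
        near <- integer(0)
        for (jy in (iy - 1):(iy + 1)) for (jx in (ix - 1):(ix + 1)) {
          if (jx >= 0 && jx < nx && jy >= 0 && jy < ny)
            near <- c(near, grid[[as.integer(jy * nx + jx + 1)]])
        }
        if (!length(near) ||
            all((xs[near] - px)^2 + (ys[near] - py)^2 >= min_separation^2)) {
          placed <- placed + 1L
          xs[placed] <- px; ys[placed] <- py
          id <- cell_id(px, py)
          grid[[id]] <- c(grid[[id]], placed)
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not place ", n, " points with min_separation ",
             min_separation, " um after ", max_tries,
             " attempts each (placed ", placed, "): request is over-dense")
      }
    }
  }
  d <- if (diameter_range) stats::runif(n, diameters[1], diameters[2]) else diameters
  new_point_set(xs, ys, d, extent, "random")
}

#' Hexagonal (honeycomb) lattice points
#'
#' Triangular lattice: every nearest-neighbour pair is separated by `pitch`.
#' Rows are `pitch*sqrt(3)/2` apart with alternate rows offset by `pitch/2`.
#'
#' @param pitch nearest-neighbour distance (um)
#' @param extent field `c(width, height)` um
#' @param diameter modulator diameter (um)
#' @export
gen_hexagonal_points <- function(pitch, extent, diameter = 50) {
  stopifnot(pitch > 0)
  w <- extent[1]; h <- extent[2]
  row_h <- pitch * sqrt(3) / 2
  iy <- 0:floor(h / row_h)
  xs <- ys <- numeric(0)
  for (r in iy) {
    off <- if (r %% 2 == 1) pitch / 2 else 0
    x <- seq(off, w, by = pitch)
    xs <- c(xs, x)
    ys <- c(ys, rep(r * row_h, length(x)))
  }
  if (!length(xs)) { xs <- w / 2; ys <- h / 2 }
  new_point_set(xs, ys, diameter, extent, "hexagonal")
}

#' Square-mesh grid points
#'
#' Cartesian grid with spacing `pitch` on both axes, corners inclusive.
#' @inheritParams gen_hexagonal_points
#' @export
gen_square_points <- function(pitch, extent, diameter = 50) {
  stopifnot(pitch > 0)
  gx <- seq(0, extent[1], by = pitch)
  gy <- seq(0, extent[2], by = pitch)
  xs <- rep(gx, times = length(gy))
  ys <- rep(gy, each = length(gx))
  new_point_set(xs, ys, diameter, extent, "regular")
}

#' Vogel spiral (sunflower) points
#'
#' Point k (k = 0..n-1) at radius `scale_c * sqrt(k)` and angle `k` times the
#' golden angle. Asymptotic areal density is `1/(pi * scale_c^2)`.
#'
#' @param n number of points before clipping to the field
#' @param scale_c radial scale constant (um)
#' @param extent field `c(width, height)` um
#' @param center spiral center, default the field center
#' @param diameter modulator diameter (um)
#' @export
gen_vogel_spiral_points <- function(n, scale_c, extent, center = extent / 2,
                                    diameter = 50) {
  stopifnot(n >= 1, scale_c > 0)
  k <- 0:(n - 1)
  r <- scale_c * sqrt(k)
  th <- k * GOLDEN_ANGLE
  xs <- center[1] + r * cos(th)
  ys <- center[2] + r * sin(th)
  keep <- xs >= 0 & xs <= extent[1] & ys >= 0 & ys <= extent[2]
  if (!any(keep)) keep[1] <- TRUE
  new_point_set(xs[keep], ys[keep], diameter, extent, "spiral")
}

#' Rasterize a point pattern into a physical thickness map
#'
#' Superposes one modulator profile per point on a raster of cell size
#' `grid_pitch`: either SiO2 cones (height at the apex, linear taper to zero at
#' the rim; overlapping cones sum) or the complement — a plate of constant
#' thickness with cylindrical holes (thickness 0 inside a hole). Pixel centers
#' sit at (i - 0.5) * grid_pitch from the field corner, y down.
#'
#' @param points a point set from one of the `gen_*_points` generators
#' @param profile `list(type = "cone", height = um)` or
#'   `list(type = "hole", plate_thickness = um)`
#' @param material material tag resolvable by [material_constants()]
#' @param grid_pitch raster cell size (um); must give >= 4 cells across the
#'   smallest modulator
#' @return object of class `mobi_mask` with fields `thickness` (um matrix),
#'   `material`, `profile`, `grid_pitch`, `topology_tag`
#' @export
rasterize_mask <- function(points, profile, material = "sio2", grid_pitch) {
  stopifnot(grid_pitch > 0)
  dmin <- if (length(points$diameters)) min(points$diameters) else Inf
  if (dmin / grid_pitch < 4) {
    stop("grid_pitch ", grid_pitch, " um too coarse for modulation diameter ",
         dmin, " um (need >= 4 cells across)")
  }
  nc <- max(1L, as.integer(round(points$extent[1] / grid_pitch)))
  nr <- max(1L, as.integer(round(points$extent[2] / grid_pitch)))
  hole <- identical(profile$type, "hole")
  thick <- matrix(0, nr, nc)
  n <- length(points$x)
  if (n > 0) {
    for (i in seq_len(n)) {
      rad <- points$diameters[i] / 2
      cx <- points$x[i] / grid_pitch + 0.5
      cy <- points$y[i] / grid_pitch + 0.5
      rpx <- rad / grid_pitch
      j0 <- max(1L, as.integer(floor(cx - rpx))); j1 <- min(nc, as.integer(ceiling(cx + rpx)))
      i0 <- max(1L, as.integer(floor(cy - rpx))); i1 <- min(nr, as.integer(ceiling(cy + rpx)))
      if (j0 > j1 || i0 > i1) next
      jj <- j0:j1; ii <- i0:i1
      ddx <- (jj - cx); ddy <- (ii - cy)
      rr <- sqrt(outer(ddy^2, ddx^2, "+")) * grid_pitch
      if (hole) {
        thick[ii, jj] <- pmax(thick[ii, jj], as.numeric(rr <= rad))
      } else {
        cone <- profile$height * pmax(1 - rr / rad, 0)
        thick[ii, jj] <- thick[ii, jj] + cone
      }
    }
  }
  if (hole) thick <- profile$plate_thickness * (1 - thick)
  m <- list(thickness = thick, material = material, profile = profile,
            grid_pitch = grid_pitch, topology_tag = points$topology_tag)
  class(m) <- "mobi_mask"
  m
}

#' @export
print.mobi_mask <- function(x, ...) {
  cat(sprintf("<mobi_mask> %s %s raster %d x %d @ %.3g um, thickness %.3g-%.3g um\n",
              x$topology_tag, x$profile$type, nrow(x$thickness), ncol(x$thickness),
              x$grid_pitch, min(x$thickness), max(x$thickness)))
  invisible(x)
}

#' Scale the modulator amplitude of a rasterized mask
#' @keywords internal
scale_mask_height <- function(mask, factor) {
  if (identical(mask$profile$type, "hole"))
    stop("hole masks have no adjustable height")
  mask$thickness <- mask$thickness * factor
  mask$profile$height <- mask$profile$height * factor
  mask
}

#' Write / read a mask as 32-bit float TIFF + JSON sidecar
#'
#' The TIFF stores the thickness map in micrometres; the sidecar records
#' material, profile, topology and raster pitch so a mask round-trips exactly
#' (to float32 precision).
#' @param mask a `mobi_mask`
#' @param path TIFF path; the sidecar is `<path>.json`
#' @export
write_mask <- function(mask, path) {
  tmax <- max(mask$thickness)
  scale <- if (tmax > 0) tmax else 1
  tiff::writeTIFF(mask$thickness / scale, path, bits.per.sample = 32L)
  meta <- list(material = mask$material, profile = mask$profile,
               topology_tag = mask$topology_tag, grid_pitch = mask$grid_pitch,
               thickness_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  img <- tiff::readTIFF(path) * meta$thickness_scale
  m <- list(thickness = img, material = meta$material, profile = meta$profile,
            grid_pitch = meta$grid_pitch, topology_tag = meta$topology_tag)
  class(m) <- "mobi_mask"
  m
}
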