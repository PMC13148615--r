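## Implicit LCS retrieval: absorption, refraction displacement and
## (directional) dark-field from K reference/sample image pairs.
##
## Founding model, per pixel and per membrane position k:
##
##   I_r,k - I_s,k = I_obj * I_r,k + D_x dI_r,k/dx + D_y dI_r,k/dy
##                   - D_f lap(I_r,k)
##
## i.e. the intensity deficit is an attenuation sink plus optical-flow
## transport of the modulation pattern by the refraction displacement
## (transport-of-intensity form) plus a diffusion term: small-angle scattering
## blurs the pattern, and to first order a blur adds (sigma^2/2) lap(I_r),
## hence the negative Laplacian coupling makes D_f >= 0 for blurring samples.
## The refraction terms ride on the pattern gradient and the dark-field term
## on its Laplacian, which is why mask topologies with richer, more isotropic
## gradient content retrieve better. Displacements are in detector pixels;
## conversion to refraction angle (via pixel_size/z2) and phase are explicit
## separate steps.

#' Build the per-pixel linear system from an image-pair series
#'
#' Rows are `[I_r, dI_r/dx, dI_r/dy, -lap I_r]` per membrane position with
#' right-hand side `I_r - I_s`; derivatives are 2nd-order central differences
#' (one-sided at borders, flagged). Requires K >= 4 for the four unknowns.
#'
#' @param pairs a `mobi_pairs`
#' @return object of class `mobi_lcs_system`
#' @export
build_lcs_system <- function(pairs) {
  K <- length(pairs$Ir)
  if (K < 4L) {
    stop("K = ", K, " membrane positions; the system has four unknowns ",
         "(I_obj, D_x, D_y, D_f) and needs K >= 4")
  }
  nr <- nrow(pairs$Ir[[1]]); nc <- ncol(pairs$Ir[[1]])
  n <- nr * nc
  Cv <- matrix(0, n, K); Cx <- matrix(0, n, K); Cy <- matrix(0, n, K)
  Cl <- matrix(0, n, K); rhs <- matrix(0, n, K)
  for (k in seq_len(K)) {
    Irk <- pairs$Ir[[k]]
    g <- image_gradient(Irk)
    Cv[, k] <- as.vector(Irk)
    Cx[, k] <- as.vector(g$dx)
    Cy[, k] <- as.vector(g$dy)
    Cl[, k] <- as.vector(-laplacian_5pt(Irk))
    rhs[, k] <- as.vector(Irk - pairs$Is[[k]])
  }
  # pixels where every derivative column vanishes carry no displacement
  # information (uniform illumination) — flagged as rank-deficient
  degen <- rowSums(abs(Cx)) + rowSums(abs(Cy)) + rowSums(abs(Cl)) == 0
  sys <- list(value = Cv, gx = Cx, gy = Cy, neg_lap = Cl, rhs = rhs,
              dim = c(nr, nc), K = K, degenerate = degen,
              border = as.vector(border_mask(nr, nc, 2L)),
              geometry = pairs$geometry)
  class(sys) <- "mobi_lcs_system"
  sys
}

#' @export
print.mobi_lcs_system <- function(x, ...) {
  cat(sprintf("<mobi_lcs_system> %d x %d px, K = %d, %d degenerate px\n",
              x$dim[1], x$dim[2], x$K, sum(x$degenerate)))
  invisible(x)
}

## neighbour-mean inpainting of flagged pixels
inpaint_mask <- function(img, bad) {
  if (!any(bad)) return(img)
  sm <- gaussian_blur(ifelse(bad, 0, img), 1.5)
  wt <- gaussian_blur(ifelse(bad, 0, 1), 1.5)
  img[bad] <- (sm / pmax(wt, 1e-9))[bad]
  img
}

## same-size box sum (w x w window, truncated at borders)
box_sum_same <- function(img, w) {
  if (w <= 1L) return(img)
  nr <- nrow(img); nc <- ncol(img)
  half <- (w - 1L) %/% 2L
  cs <- apply(apply(img, 2, cumsum), 1, cumsum)
  cs <- t(cs)
  pad <- matrix(0, nr + 1, nc + 1); pad[-1, -1] <- cs
  r1 <- pmax(seq_len(nr) - half - 1L, 0L); r2 <- pmin(seq_len(nr) + half, nr)
  c1 <- pmax(seq_len(nc) - half - 1L, 0L); c2 <- pmin(seq_len(nc) + half, nc)
  pad[r2 + 1L, c2 + 1L] - pad[r1 + 1L, c2 + 1L] -
    pad[r2 + 1L, c1 + 1L] + pad[r1 + 1L, c1 + 1L]
}

#' Solve the LCS system per pixel
#'
#' Tikhonov-damped least squares on the per-pixel normal equations; the
#' damping of each column is scaled to its mean-square magnitude so `lambda`
#' is a single dimensionless knob (default `1e-3`). Rank-deficient pixels
#' fall back to the minimum-norm solution, are flagged, and inpainted from
#' neighbours. `pool_w > 1` pools the equations of a `pool_w x pool_w`
#' neighbourhood into each pixel's system (robustness knob; the default 1
#' is the plain per-pixel method).
#'
#' @param system a `mobi_lcs_system`
#' @param lambda relative Tikhonov damping (>= 0)
#' @param clip_df clip negative dark-field to zero (flag kept in `n_clipped`)
#' @param pool_w odd neighbourhood width for equation pooling (default 1)
#' @return object of class `mobi_retrieval` with matrices `I_obj`, `D_x`,
#'   `D_y`, `D_f`, `residual`, counts of degenerate pixels, and the geometry
#' @export
solve_lcs <- function(system, lambda = 1e-3, clip_df = FALSE, pool_w = 1L) {
  stopifnot(lambda >= 0, pool_w >= 1L, pool_w %% 2 == 1)
  cols <- list(system$value, system$gx, system$gy, system$neg_lap)
  P <- 4L
  n <- nrow(system$rhs)
  G <- matrix(0, n, P * (P + 1) / 2)
  B <- matrix(0, n, P)
  q <- 1L
  for (r in seq_len(P)) {
    for (cc in r:P) {
      G[, q] <- rowSums(cols[[r]] * cols[[cc]])
      q <- q + 1L
    }
    B[, r] <- rowSums(cols[[r]] * system$rhs)
  }
  d <- system$dim
  if (pool_w > 1L) {
    for (j in seq_len(ncol(G))) G[, j] <- as.vector(box_sum_same(matrix(G[, j], d[1], d[2]), pool_w))
    for (j in seq_len(P)) B[, j] <- as.vector(box_sum_same(matrix(B[, j], d[1], d[2]), pool_w))
  }
  scales <- c(mean(system$value^2), mean(system$gx^2), mean(system$gy^2),
              mean(system$neg_lap^2)) * system$K * pool_w^2
  lam <- lambda * pmax(scales, max(scales) * 1e-12)
  sol <- solve_normal_batch(G, B, lam)
  # per-pixel rms residual of the unpooled system
  res2 <- 0
  for (k in seq_len(system$K)) {
    pred <- cols[[1]][, k] * sol[, 1] + cols[[2]][, k] * sol[, 2] +
      cols[[3]][, k] * sol[, 3] + cols[[4]][, k] * sol[, 4]
    res2 <- res2 + (pred - system$rhs[, k])^2
  }
  bad <- system$degenerate | sol[, P + 1] > 0
  mk <- function(j) inpaint_mask(matrix(sol[, j], d[1], d[2]),
                                 matrix(bad, d[1], d[2]))
  res <- list(I_obj = mk(1), D_x = mk(2), D_y = mk(3), D_f = mk(4),
              residual = matrix(sqrt(res2 / system$K), d[1], d[2]),
              n_degenerate = sum(bad), n_clipped = 0L,
              border = matrix(system$border, d[1], d[2]),
              geometry = system$geometry)
  if (clip_df) {
    res$n_clipped <- sum(res$D_f < 0)
    res$D_f <- pmax(res$D_f, 0)
  }
  class(res) <- "mobi_retrieval"
  res
}

#' @export
print.mobi_retrieval <- function(x, ...) {
  cat(sprintf("<mobi_retrieval> %d x %d px; D_y range [%.3g, %.3g] px; %d degenerate px\n",
              nrow(x$D_y), ncol(x$D_y), min(x$D_y), max(x$D_y), x$n_degenerate))
  invisible(x)
}

#' Retrieve absorption, refraction and dark-field from a pair series
#'
#' Convenience wrapper: [build_lcs_system()] then [solve_lcs()].
#' @inheritParams build_lcs_system
#' @inheritParams solve_lcs
#' @export
lcs_retrieve <- function(pairs, lambda = 1e-3, clip_df = FALSE) {
  solve_lcs(build_lcs_system(pairs), lambda = lambda, clip_df = clip_df)
}

#' Integrate displacement maps into a phase map
#'
#' Displacements (detector px) convert to refraction angles via
#' `alpha = D * pixel_size / z2`; the transverse phase gradient is
#' `(2 pi / lambda) * alpha * pixel_size` per pixel step, and the potential is
#' recovered by least-squares integration in the Fourier domain
#' (Frankot-Chellappa, periodic boundary), reported zero-mean. NaNs are
#' treated as masked and set to zero gradient before integration.
#'
#' @param D_x,D_y displacement maps (detector pixels)
#' @param geometry an [acquisition_geometry()]
#' @return phase map (radians, zero mean) of class `mobi_phase`
#' @export
integrate_phase <- function(D_x, D_y, geometry) {
  ax <- displacement_to_angle(D_x, geometry)
  ay <- displacement_to_angle(D_y, geometry)
  k <- 2 * pi / geometry$wavelength
  gx <- k * ax * geometry$pixel_size * 1e-6
  gy <- k * ay * geometry$pixel_size * 1e-6
  gx[!is.finite(gx)] <- 0; gy[!is.finite(gy)] <- 0
  phi <- fourier_integrate(gx, gy)
  class(phi) <- c("mobi_phase", class(phi))
  phi
}

#' Least-squares integration of a gradient field (Fourier domain)
#' @param gx,gy gradient per pixel step
#' @return zero-mean potential matrix
#' @export
fourier_integrate <- function(gx, gy) {
  nr <- nrow(gx); nc <- ncol(gx)
  # Frankot-Chellappa least squares: phase_hat = -i (f.G_hat) / (2 pi |f|^2)
  fy <- fft_freq(nr); fx <- fft_freq(nc)
  FY <- matrix(fy, nr, nc); FX <- matrix(fx, nr, nc, byrow = TRUE)
  q <- 2 * pi * (FX^2 + FY^2)
  q[1, 1] <- Inf  # DC offset is unobservable; reported zero-mean
  Phat <- -1i * (FX * stats::fft(gx) + FY * stats::fft(gy)) / q
  phi <- Re(stats::fft(Phat, inverse = TRUE)) / (nr * nc)
  phi - mean(phi)
}

#' Directional (tensor) dark-field retrieval
#'
#' Replaces the scalar diffusion term by a symmetric 2x2 scattering tensor
#' coupling to the second derivatives of the reference:
#' `- [t_xx d2/dx2 + 2 t_xy d2/dxdy + t_yy d2/dy2] I_r`, giving six unknowns
#' per pixel (K >= 6). Eigen-decomposition yields semi-axes a >= b >= 0 and
#' the orientation psi of the principal axis in [0, pi); non-PSD pixels are
#' clipped to the nearest PSD tensor and counted.
#'
#' @param pairs a `mobi_pairs` with K >= 6
#' @param lambda relative Tikhonov damping
#' @return list with tensor component maps `t_xx`, `t_xy`, `t_yy`, semi-axis
#'   maps `a`, `b`, orientation `psi`, `n_clipped`, and `I_obj`, `D_x`, `D_y`
#' @export
directional_darkfield <- function(pairs, lambda = 1e-3) {
  K <- length(pairs$Ir)
  if (K < 6L) {
    stop("K = ", K, " membrane positions; the tensor dark-field system has ",
         "six unknowns and needs K >= 6")
  }
  nr <- nrow(pairs$Ir[[1]]); nc <- ncol(pairs$Ir[[1]]); n <- nr * nc
  Cv <- matrix(0, n, K); Cx <- matrix(0, n, K); Cy <- matrix(0, n, K)
  Cxx <- matrix(0, n, K); Cxy <- matrix(0, n, K); Cyy <- matrix(0, n, K)
  rhs <- matrix(0, n, K)
  for (k in seq_len(K)) {
    Irk <- pairs$Ir[[k]]
    g <- image_gradient(Irk)
    h <- image_hessian(Irk)
    Cv[, k] <- as.vector(Irk)
    Cx[, k] <- as.vector(g$dx); Cy[, k] <- as.vector(g$dy)
    Cxx[, k] <- as.vector(-h$dxx)
    Cxy[, k] <- as.vector(-2 * h$dxy)
    Cyy[, k] <- as.vector(-h$dyy)
    rhs[, k] <- as.vector(Irk - pairs$Is[[k]])
  }
  scales <- vapply(list(Cv, Cx, Cy, Cxx, Cxy, Cyy), function(m) mean(m^2), 0)
  lam <- lambda * pmax(scales, max(scales) * 1e-12)
  sol <- lcs_solve_batch(list(Cv, Cx, Cy, Cxx, Cxy, Cyy), rhs, lam)
  txx <- sol[, 4]; txy <- sol[, 5]; tyy <- sol[, 6]
  # closed-form symmetric 2x2 eigen-decomposition
  tr2 <- (txx + tyy) / 2
  rad <- sqrt(((txx - tyy) / 2)^2 + txy^2)
  l1 <- tr2 + rad; l2 <- tr2 - rad
  n_clipped <- sum(l2 < 0 | l1 < 0)
  l1c <- pmax(l1, 0); l2c <- pmax(l2, 0)
  psi <- atan2(2 * txy, txx - tyy) / 2
  psi <- (psi + pi) %% pi
  shape <- function(v) matrix(v, nr, nc)
  out <- list(
    I_obj = shape(sol[, 1]), D_x = shape(sol[, 2]), D_y = shape(sol[, 3]),
    t_xx = shape(txx), t_xy = shape(txy), t_yy = shape(tyy),
    a = shape(sqrt(l1c)), b = shape(sqrt(l2c)), psi = shape(psi),
    n_clipped = n_clipped, residual = shape(sol[, 7]),
    geometry = pairs$geometry)
  class(out) <- "mobi_ddf"
  out
}

#' HSV encoding of a directional dark-field result
#'
#' Hue encodes the principal-axis angle (mod pi), saturation the length of the
#' principal semi-axis, and value the tensor norm `sqrt(a^2 + b^2)`;
#' saturation and value are normalized by their given (or 99th percentile)
#' scales. Returns an rgb array `[nr, nc, 3]` in 0-1.
#'
#' @param ddf result of [directional_darkfield()]
#' @param sat_scale,val_scale normalization scales (default robust maxima)
#' @export
ddf_to_hsv <- function(ddf, sat_scale = NULL, val_scale = NULL) {
  val <- sqrt(ddf$a^2 + ddf$b^2)
  sat <- ddf$a
  if (is.null(sat_scale)) sat_scale <- stats::quantile(sat, 0.99)
  if (is.null(val_scale)) val_scale <- stats::quantile(val, 0.99)
  h <- as.vector(ddf$psi / pi)
  s <- pmin(as.vector(sat) / max(sat_scale, 1e-12), 1)
  v <- pmin(as.vector(val) / max(val_scale, 1e-12), 1)
  cols <- grDevices::hsv(h, s, v)
  rgb <- grDevices::col2rgb(cols) / 255
  arr <- array(0, c(nrow(ddf$a), ncol(ddf$a), 3))
  arr[, , 1] <- matrix(rgb[1, ], nrow(ddf$a))
  arr[, , 2] <- matrix(rgb[2, ], nrow(ddf$a))
  arr[, , 3] <- matrix(rgb[3, ], nrow(ddf$a))
  arr
}

#' Export retrieval channels as 32-bit float TIFFs
#' @param retrieval a `mobi_retrieval`
#' @param dir output directory
#' @export
write_retrieval <- function(retrieval, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in c("I_obj", "D_x", "D_y", "D_f", "residual")) {
    img <- retrieval[[ch]]
    rng <- max(abs(img), 1e-12)
    tiff::writeTIFF((img / rng + 1) / 2, file.path(dir, paste0(ch, ".tif")),
                    bits.per.sample = 32L)
    jsonlite::write_json(list(channel = ch, scale = rng, offset = "symmetric"),
                         file.path(dir, paste0(ch, ".tif.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
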