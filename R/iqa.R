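## Image-quality assessment of retrieved displacement maps.
##
## All indices operate on displacement (D) maps, which carry the phase
## information without the artefacts of an integration step; phase maps
## (class `mobi_phase`) are rejected by construction.

assert_dmap <- function(...) {
  for (m in list(...)) {
    if (inherits(m, "mobi_phase")) {
      stop("image-quality indices are defined on displacement maps, ",
           "not integrated phase; pass D_x/D_y")
    }
    stopifnot(is.matrix(m))
  }
}

#' Theoretical (ideal) displacement maps of a phantom
#'
#' The noise-free displacement the phantom imprints on the modulation
#' pattern: refraction angle `alpha = grad(delta t)` w.r.t. physical
#' sample-plane coordinates, landing on the detector displaced by `z2 alpha`,
#' i.e. `D0 = z2 grad(delta t) / pixel_size` detector pixels.
#'
#' @param sample a `mobi_thickness` on a detector-conjugate grid
#' @param geometry an [acquisition_geometry()]
#' @param os oversampling of the sample grid (result is binned to detector)
#' @return list with matrices `D0_x`, `D0_y` (detector px)
#' @export
theoretical_displacement <- function(sample, geometry, os = 1L) {
  opt <- sample_optics(sample, geometry)
  dx <- opt$dx_px; dy <- opt$dy_px
  if (os > 1L) { dx <- bin_image(dx, os); dy <- bin_image(dy, os) }
  list(D0_x = dx, D0_y = dy)
}

#' Normalized root-mean-square error
#'
#' `||D - D0|| / ||D0||`: the RMSE normalized by the Euclidean norm of the
#' reference map. Lower is better; 0 means identity.
#'
#' @param D retrieved map
#' @param D0 theoretical reference map
#' @export
nrmse <- function(D, D0) {
  assert_dmap(D, D0)
  stopifnot(all(dim(D) == dim(D0)))
  n0 <- sqrt(sum(D0^2))
  if (n0 == 0) stop("reference map has zero norm; NRMSE undefined")
  sqrt(sum((D - D0)^2)) / n0
}

## uniform box filter via cumulative sums (valid region only)
box_filter_valid <- function(img, w) {
  nr <- nrow(img); nc <- ncol(img)
  stopifnot(nr >= w, nc >= w)
  cs <- apply(apply(img, 2, cumsum), 1, cumsum)  # transposed integral image
  cs <- t(cs)
  pad <- matrix(0, nr + 1, nc + 1)
  pad[-1, -1] <- cs
  i <- seq_len(nr - w + 1); j <- seq_len(nc - w + 1)
  (pad[i + w, j + w] - pad[i, j + w] - pad[i + w, j] + pad[i, j]) / (w * w)
}

#' Structural similarity index (uniform window)
#'
#' Two-term SSIM with stabilizers `c1 = (k1 L)^2`, `c2 = (k2 L)^2`; the
#' window is a `window x window` uniform average (7 by default) and the index
#' is the mean over all valid windows. `L` defaults to the dynamic range of
#' the stacked pair.
#'
#' @param x,y maps to compare
#' @param window odd window size
#' @param k1,k2 stabilizer constants
#' @param L dynamic range (default `max - min` over both maps)
#' @export
ssim <- function(x, y, window = 7L, k1 = 0.01, k2 = 0.03, L = NULL) {
  assert_dmap(x, y)
  stopifnot(all(dim(x) == dim(y)), window %% 2 == 1)
  if (min(dim(x)) < window) stop("image smaller than the SSIM window")
  if (is.null(L)) L <- max(x, y) - min(x, y)
  if (L == 0) L <- 1
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  mx <- box_filter_valid(x, window); my <- box_filter_valid(y, window)
  vx <- box_filter_valid(x * x, window) - mx^2
  vy <- box_filter_valid(y * y, window) - my^2
  cxy <- box_filter_valid(x * y, window) - mx * my
  s <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  mean(s)
}

## contrast-structure term only (for MS-SSIM intermediate scales)
ssim_cs <- function(x, y, window = 7L, k2 = 0.03, L = 1) {
  c2 <- (k2 * L)^2
  mx <- box_filter_valid(x, window); my <- box_filter_valid(y, window)
  vx <- box_filter_valid(x * x, window) - mx^2
  vy <- box_filter_valid(y * y, window) - my^2
  cxy <- box_filter_valid(x * y, window) - mx * my
  mean((2 * cxy + c2) / (vx + vy + c2))
}

## dyadic downsample: 2x2 block mean
downsample2 <- function(img) {
  nr <- 2L * (nrow(img) %/% 2L); nc <- 2L * (ncol(img) %/% 2L)
  bin_image(img[seq_len(nr), seq_len(nc)], 2L)
}

#' Multi-scale structural similarity
#'
#' Standard 5-scale combination: contrast-structure terms at every scale,
#' luminance at the coarsest, weights (0.0448, 0.2856, 0.3001, 0.2363,
#' 0.1333), combined as a weighted geometric mean. Falls back to fewer scales
#' on small images.
#'
#' @inheritParams ssim
#' @export
ms_ssim <- function(x, y, window = 7L, k1 = 0.01, k2 = 0.03, L = NULL) {
  assert_dmap(x, y)
  if (is.null(L)) L <- max(x, y) - min(x, y)
  if (L == 0) L <- 1
  w <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
  nsc <- min(5L, max(1L, floor(log2(min(dim(x)) / window)) + 1L))
  w <- w[seq_len(nsc)] / sum(w[seq_len(nsc)])
  vals <- numeric(nsc)
  for (s in seq_len(nsc)) {
    if (s < nsc) {
      vals[s] <- ssim_cs(x, y, window, k2, L)
      x <- downsample2(x); y <- downsample2(y)
    } else {
      vals[s] <- ssim(x, y, window, k1, k2, L)
    }
  }
  # terms can be slightly negative on anticorrelated noise; clamp for the
  # geometric mean and report 0 in that regime
  if (any(vals <= 0)) return(0)
  prod(vals^w)
}

## spectral-residual visual saliency map (Hou & Zhang construction)
spectral_residual_saliency <- function(img, avg_w = 3L, blur_sigma = 2.5) {
  F <- stats::fft(img)
  logamp <- log(Mod(F) + 1e-12)
  ph <- Arg(F)
  # local average of the log spectrum (periodic smoothing)
  la <- gaussian_blur(logamp, avg_w / 3)
  sr <- logamp - la
  sal <- Mod(stats::fft(exp(sr + 1i * ph), inverse = TRUE) / length(img))^2
  gaussian_blur(sal, blur_sigma)
}

#' Spectral residual similarity (SR-SIM)
#'
#' Combines spectral-residual saliency similarity with gradient-magnitude
#' similarity, weighted by the pointwise maximum saliency. Maps are first
#' rescaled to a 0-255 dynamic range so the published stabilizers apply.
#'
#' @inheritParams ssim
#' @param c1 saliency stabilizer (published 0.40)
#' @param c2 gradient stabilizer (published 225 for 8-bit range)
#' @param alpha gradient-term exponent (published 0.50)
#' @export
sr_sim <- function(x, y, c1 = 0.40, c2 = 225, alpha = 0.50) {
  assert_dmap(x, y)
  rng <- max(x, y) - min(x, y); if (rng == 0) rng <- 1
  lo <- min(x, y)
  x <- (x - lo) / rng * 255; y <- (y - lo) / rng * 255
  v1 <- spectral_residual_saliency(x); v2 <- spectral_residual_saliency(y)
  g1 <- with(image_gradient(x), sqrt(dx^2 + dy^2))
  g2 <- with(image_gradient(y), sqrt(dx^2 + dy^2))
  sv <- (2 * v1 * v2 + c1) / (v1^2 + v2^2 + c1)
  sg <- (2 * g1 * g2 + c2) / (g1^2 + g2^2 + c2)
  wmap <- pmax(v1, v2)
  sum(sv * sg^alpha * wmap) / sum(wmap)
}

#' Visual saliency-induced index (VSI), grayscale form
#'
#' Saliency-weighted combination of saliency similarity and gradient
#' similarity. For single-channel displacement maps the chromatic terms of
#' the published index drop out; saliency here is the spectral-residual map
#' with a center prior, a standard stand-in for the SDSP detector on
#' grayscale data.
#'
#' @inheritParams ssim
#' @param c1 saliency stabilizer
#' @param c2 gradient stabilizer
#' @param alpha gradient exponent
#' @export
vsi <- function(x, y, c1 = 1.27, c2 = 386, alpha = 0.40) {
  assert_dmap(x, y)
  rng <- max(x, y) - min(x, y); if (rng == 0) rng <- 1
  lo <- min(x, y)
  x <- (x - lo) / rng * 255; y <- (y - lo) / rng * 255
  nr <- nrow(x); nc <- ncol(x)
  cy <- ((seq_len(nr) - nr / 2) / nr)^2
  cx <- ((seq_len(nc) - nc / 2) / nc)^2
  prior <- exp(-outer(cy, cx, "+") / 0.25)
  v1 <- spectral_residual_saliency(x) * prior
  v2 <- spectral_residual_saliency(y) * prior
  v1 <- v1 / max(v1); v2 <- v2 / max(v2)
  g1 <- with(image_gradient(x), sqrt(dx^2 + dy^2))
  g2 <- with(image_gradient(y), sqrt(dx^2 + dy^2))
  sv <- (2 * v1 * v2 + c1) / (v1^2 + v2^2 + c1)
  sg <- (2 * g1 * g2 + c2) / (g1^2 + g2^2 + c2)
  wmap <- pmax(v1, v2)
  sum(sv * sg^alpha * wmap) / sum(wmap)
}

#' Fourier ring correlation between two independent realizations
#'
#' Per-ring normalized cross-correlation of the two maps' spectra,
#' `Re<F_a F_b*> / sqrt(<|F_a|^2><|F_b|^2>)`, in rings of one frequency bin.
#' The resolution is `1/f` (pixels) at the first downward crossing of the 1/7
#' threshold, linearly interpolated between rings; curves that never cross
#' are flagged and assigned the two-pixel Nyquist resolution.
#'
#' @param D_a,D_b two maps of the same scene from independent realizations
#' @param threshold crossing threshold (default 1/7)
#' @param apodize apply a Hann window before the FFT (default FALSE)
#' @return object of class `mobi_frc`: `frequencies` (cycles/px),
#'   `correlation`, `threshold`, `resolution_px`, `crossed`
#' @export
frc <- function(D_a, D_b, threshold = 1 / 7, apodize = FALSE) {
  assert_dmap(D_a, D_b)
  stopifnot(all(dim(D_a) == dim(D_b)))
  nr <- nrow(D_a); nc <- ncol(D_a)
  if (apodize) {
    wy <- 0.5 - 0.5 * cos(2 * pi * seq_len(nr) / (nr + 1))
    wx <- 0.5 - 0.5 * cos(2 * pi * seq_len(nc) / (nc + 1))
    W <- outer(wy, wx)
    D_a <- D_a * W; D_b <- D_b * W
  }
  Fa <- stats::fft(D_a - mean(D_a)); Fb <- stats::fft(D_b - mean(D_b))
  fy <- fft_freq(nr); fx <- fft_freq(nc)
  fr <- sqrt(outer(fy^2, fx^2, "+"))
  nbin <- floor(min(nr, nc) / 2)
  bins <- pmin(1L + as.integer(floor(fr * 2 * nbin)), nbin + 1L)  # df = 0.5/nbin
  num <- tapply(as.vector(Re(Fa * Conj(Fb))), as.vector(bins), sum)
  da <- tapply(as.vector(Mod(Fa)^2), as.vector(bins), sum)
  db <- tapply(as.vector(Mod(Fb)^2), as.vector(bins), sum)
  keep <- as.integer(names(num)) <= nbin
  corr <- as.vector(num[keep] / sqrt(pmax(da[keep] * db[keep], 1e-300)))
  freqs <- (as.integer(names(num))[keep] - 0.5) * (0.5 / nbin)
  # drop the DC-dominated first bin from crossing detection
  below <- which(corr < threshold & freqs > 0.02)
  if (length(below)) {
    i <- below[1]
    if (i == 1) {
      fcross <- freqs[1]
    } else {
      f0 <- freqs[i - 1]; f1 <- freqs[i]
      c0 <- corr[i - 1]; c1 <- corr[i]
      fcross <- f0 + (c0 - threshold) / (c0 - c1) * (f1 - f0)
    }
    res <- 1 / fcross
    crossed <- TRUE
  } else {
    res <- 2
    crossed <- FALSE
  }
  out <- list(frequencies = freqs, correlation = corr, threshold = threshold,
              resolution_px = res, crossed = crossed)
  class(out) <- "mobi_frc"
  out
}

#' @export
print.mobi_frc <- function(x, ...) {
  cat(sprintf("<mobi_frc> resolution %.3g px at threshold %.3g%s\n",
              x$resolution_px, x$threshold,
              if (x$crossed) "" else " (no crossing; Nyquist floor)"))
  invisible(x)
}

#' Auto-place measurement windows in the sample-free zone
#'
#' Tiles of `win` size are placed along the image border, skipping any tile
#' that intersects the (dilated) phantom footprint, until `n` are found.
#'
#' @param support logical matrix, TRUE on the phantom footprint
#' @param n number of windows
#' @param win `c(rows, cols)` window size
#' @param margin border pixels to avoid (one-sided derivative zone)
#' @return list of `n` lists with `rows`, `cols` index vectors
#' @export
place_windows <- function(support, n = 8L, win = c(5L, 40L), margin = 4L) {
  nr <- nrow(support); nc <- ncol(support)
  sup <- gaussian_blur(support * 1, 2) > 0.01  # safety dilation
  cand <- list()
  r_all <- seq(margin + 1L, nr - margin - win[1] + 1L, by = win[1])
  c_all <- seq(margin + 1L, nc - margin - win[2] + 1L, by = win[2])
  # walk the border ring first (outermost tiles), then move inward
  ring <- expand.grid(r0 = r_all, c0 = c_all)
  ring$depth <- pmin(pmin(ring$r0 - 1L, nr - win[1] + 1L - ring$r0),
                     pmin(ring$c0 - 1L, nc - win[2] + 1L - ring$c0))
  ring <- ring[order(ring$depth), ]
  for (i in seq_len(nrow(ring))) {
    rows <- ring$r0[i]:(ring$r0[i] + win[1] - 1L)
    cols <- ring$c0[i]:(ring$c0[i] + win[2] - 1L)
    if (!any(sup[rows, cols])) {
      cand[[length(cand) + 1L]] <- list(rows = rows, cols = cols)
    }
  }
  if (length(cand) < n) stop("could not place ", n, " sample-free windows")
  # outermost tiles, spread around the ring
  idx <- unique(round(seq(1, min(length(cand), 4L * n), length.out = n)))
  cand[idx[seq_len(n)]]
}

#' Angular sensitivity from sample-free windows
#'
#' Standard deviation of the retrieved vertical refraction angle
#' `alpha_y = D_y pixel_size / z2` in each window; reported as mean and
#' standard error over the windows, in nanoradians. The windows must avoid
#' the phantom support.
#'
#' @param D_y retrieved displacement map (pixels)
#' @param geometry an [acquisition_geometry()]
#' @param windows list from [place_windows()]
#' @param support optional footprint to validate window placement against
#' @return list with `mean_nrad`, `se_nrad`, `per_window_nrad`
#' @export
angular_sensitivity <- function(D_y, geometry, windows, support = NULL) {
  assert_dmap(D_y)
  vals <- vapply(windows, function(w) {
    if (!is.null(support) && any(support[w$rows, w$cols])) {
      stop("sensitivity window overlaps the sample support")
    }
    stats::sd(displacement_to_angle(D_y[w$rows, w$cols], geometry))
  }, 0)
  vals <- vals * 1e9
  list(mean_nrad = mean(vals),
       se_nrad = stats::sd(vals) / sqrt(length(vals)),
       per_window_nrad = vals)
}

#' Signal-to-noise ratio between two ROIs
#'
#' `mean(signal - mean(background)) / sd(background)`; used for dark-field
#' maps and for the saturation channel of directional dark-field.
#'
#' @param map image matrix
#' @param roi_signal,roi_background lists with `rows`, `cols`
#' @export
snr <- function(map, roi_signal, roi_background) {
  assert_dmap(map)
  bg <- map[roi_background$rows, roi_background$cols]
  sg <- map[roi_signal$rows, roi_signal$cols]
  if (length(bg) < 2 || length(sg) < 1) stop("degenerate ROI")
  s <- stats::sd(bg)
  if (s == 0) stop("background ROI has zero variance")
  (mean(sg) - mean(bg)) / s
}
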