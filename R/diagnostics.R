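## Explanatory diagnostics of reference images: intensity-gradient
## distributions (values and orientations) and modulation packing density.
## These quantify why a mask topology retrieves well: rich, isotropic
## gradient content and a dense, even paving of modulations.

#' Gradient statistics of reference images
#'
#' Central-difference gradients of a single reference (or of the pixelwise
#' sum of a shifted stack); histogram of gradient magnitudes on a fixed
#' binning, and a magnitude-weighted histogram of gradient orientations
#' `atan2(dy, dx)` over `[-pi, pi)`. The orientation entropy (nats) is the
#' summary statistic: maximal for isotropic patterns, low when the mass
#' concentrates on lattice axes.
#'
#' @param images a matrix, or list of matrices (summed when
#'   `scope = "sum_of_K"`)
#' @param scope "single_reference" (first image) or "sum_of_K"
#' @param n_bins_mag,n_bins_orient histogram binning
#' @return object of class `mobi_gradient_stats`
#' @export
gradient_stats <- function(images, scope = c("single_reference", "sum_of_K"),
                           n_bins_mag = 64L, n_bins_orient = 36L) {
  scope <- match.arg(scope)
  if (is.matrix(images)) images <- list(images)
  img <- if (scope == "sum_of_K") Reduce(`+`, images) else images[[1]]
  g <- image_gradient(img)
  mag <- sqrt(g$dx^2 + g$dy^2)
  ori <- atan2(g$dy, g$dx)
  flat <- max(mag) == 0
  if (flat) {
    mh <- rep(0, n_bins_mag); oh <- rep(0, n_bins_orient)
  } else {
    mb <- seq(0, max(mag), length.out = n_bins_mag + 1L)
    mh <- as.vector(table(cut(as.vector(mag), mb, include.lowest = TRUE)))
    mh <- mh / sum(mh)
    ob <- seq(-pi, pi, length.out = n_bins_orient + 1L)
    w <- as.vector(mag)
    oc <- cut(as.vector(ori), ob, include.lowest = TRUE)
    oh <- as.vector(tapply(w, oc, sum, default = 0))
    oh[is.na(oh)] <- 0
    oh <- oh / sum(oh)
  }
  p <- oh[oh > 0]
  out <- list(magnitude_histogram = mh,
              orientation_histogram = oh,
              orientation_breaks = seq(-pi, pi, length.out = n_bins_orient + 1L),
              mean_magnitude = mean(mag), sd_magnitude = stats::sd(as.vector(mag)),
              orientation_entropy = if (length(p)) -sum(p * log(p)) else NA_real_,
              flat = flat, scope = scope)
  class(out) <- "mobi_gradient_stats"
  out
}

#' @export
print.mobi_gradient_stats <- function(x, ...) {
  cat(sprintf("<mobi_gradient_stats> %s: mean |grad| %.4g, orientation entropy %.4g nats%s\n",
              x$scope, x$mean_magnitude, x$orientation_entropy,
              if (x$flat) " (flat image)" else ""))
  invisible(x)
}

#' Chi-squared isotropy test of an orientation histogram
#'
#' Tests the magnitude-weighted orientation histogram against uniformity.
#' Weighted counts are rescaled to the number of contributing pixels so the
#' test statistic has the nominal scale.
#' @param gs a `mobi_gradient_stats`
#' @param n_eff effective count (default: 20 per histogram bin — orientation
#'   samples are strongly correlated within a modulation, so the nominal
#'   pixel count grossly overstates the information)
#' @return p-value
#' @export
orientation_isotropy_pvalue <- function(gs, n_eff = NULL) {
  h <- gs$orientation_histogram
  if (gs$flat) return(NA_real_)
  if (is.null(n_eff)) n_eff <- length(h) * 20
  counts <- h * n_eff
  stats::chisq.test(counts)$p.value
}

#' Detect modulation centers in a reference image
#'
#' Difference-of-Gaussians band-pass tuned to the design peak-to-peak
#' spacing, then 3x3 local maxima above a prominence threshold (a fraction
#' of the band-passed amplitude range).
#'
#' @param I_r reference image
#' @param spacing_px design modulation spacing (detector px)
#' @param prominence fraction of the band-passed amplitude required
#' @return integer matrix `cbind(row, col)` of detected centers
#' @export
detect_modulations <- function(I_r, spacing_px, prominence = 0.10,
                               polarity = c("auto", "bright", "dark")) {
  polarity <- match.arg(polarity)
  s1 <- spacing_px / 4; s2 <- spacing_px / 1.6
  bp <- gaussian_blur(I_r, s1) - gaussian_blur(I_r, s2)
  med <- stats::median(bp)
  if (polarity == "auto") {
    # absorbing modulators (cones, Ni plate between holes) are intensity
    # minima; transmissive ones are maxima — pick the stronger tail
    polarity <- if (abs(min(bp) - med) > abs(max(bp) - med)) "dark" else "bright"
  }
  bp <- if (polarity == "dark") med - bp else bp - med
  nr <- nrow(bp); nc <- ncol(bp)
  mx <- matrix(-Inf, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- pmin(pmax(seq_len(nr) + dr, 1), nr)
    cs <- pmin(pmax(seq_len(nc) + dc, 1), nc)
    mx <- pmax(mx, bp[rs, cs])
  }
  thr <- prominence * max(bp)
  # >= admits plateau ties (a modulation centered on a pixel boundary);
  # non-maximum suppression below keeps one detection per modulation
  peaks <- which(bp >= mx & bp > thr, arr.ind = TRUE)
  colnames(peaks) <- c("row", "col")
  if (nrow(peaks) > 1) {
    o <- order(bp[peaks], decreasing = TRUE)
    peaks <- peaks[o, , drop = FALSE]
    keep <- rep(TRUE, nrow(peaks))
    min_d2 <- (spacing_px / 2)^2
    for (i in seq_len(nrow(peaks))[-1]) {
      prev <- which(keep[seq_len(i - 1)])
      if (any((peaks[prev, 1] - peaks[i, 1])^2 +
              (peaks[prev, 2] - peaks[i, 2])^2 < min_d2)) keep[i] <- FALSE
    }
    peaks <- peaks[keep, , drop = FALSE]
  }
  peaks
}

#' Modulation packing-density map
#'
#' Counts detected modulations in sliding windows and reports modulations per
#' squared pixel; the spatial uniformity of this density governs the local
#' availability of information for retrieval.
#'
#' @param I_r reference image
#' @param spacing_px design modulation spacing (px); must not exceed `window`
#' @param window sliding window size (px)
#' @param stride window stride (px)
#' @param prominence passed to [detect_modulations()]
#' @return object of class `mobi_density_map` with the density matrix, its
#'   `mean` and `sd`, and the detected centers
#' @export
packing_density <- function(I_r, spacing_px, window = 32L, stride = 8L,
                            prominence = 0.10) {
  if (window < spacing_px) {
    stop("window (", window, " px) smaller than the modulation spacing (",
         spacing_px, " px)")
  }
  centers <- detect_modulations(I_r, spacing_px, prominence)
  nr <- nrow(I_r); nc <- ncol(I_r)
  r0 <- seq(1L, nr - window + 1L, by = stride)
  c0 <- seq(1L, nc - window + 1L, by = stride)
  dens <- matrix(0, length(r0), length(c0))
  for (i in seq_along(r0)) {
    inr <- centers[, 1] >= r0[i] & centers[, 1] < r0[i] + window
    if (!any(inr)) next
    cc <- centers[inr, 2]
    for (j in seq_along(c0)) {
      dens[i, j] <- sum(cc >= c0[j] & cc < c0[j] + window)
    }
  }
  dens <- dens / window^2
  out <- list(density = dens, window = window, stride = stride,
              mean = mean(dens), sd = stats::sd(as.vector(dens)),
              n_detected = nrow(centers), centers = centers)
  class(out) <- "mobi_density_map"
  out
}

#' @export
print.mobi_density_map <- function(x, ...) {
  cat(sprintf("<mobi_density_map> %.4g +/- %.4g modulations/px^2 (%d detected, window %d px)\n",
              x$mean, x$sd, x$n_detected, x$window))
  invisible(x)
}
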