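## Low-level image helpers shared by the simulation and retrieval code.
## Images are plain numeric matrices indexed [row, col] = [y, x], y increasing
## downward (image convention). All FFT-based helpers assume periodic wrap;
## callers that care about edges pad first.

#' Discrete Fourier frequencies for one axis
#'
#' @param n number of samples
#' @return frequencies in cycles/sample, ordered as `stats::fft` output
#' @keywords internal
fft_freq <- function(n) {
  k <- 0:(n - 1)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k / n
}

#' Gaussian blur of a matrix via the frequency domain
#'
#' Periodic boundary; exact Gaussian transfer function, so repeated blurs
#' compose as variances add.
#'
#' @param img numeric matrix
#' @param sigma standard deviation in pixels (scalar, or length-2 `c(sy, sx)`)
#' @return blurred matrix
#' @export
gaussian_blur <- function(img, sigma) {
  if (length(sigma) == 1L) sigma <- c(sigma, sigma)
  if (all(sigma <= 0)) return(img)
  fy <- fft_freq(nrow(img))
  fx <- fft_freq(ncol(img))
  hy <- exp(-2 * pi^2 * sigma[1]^2 * fy^2)
  hx <- exp(-2 * pi^2 * sigma[2]^2 * fx^2)
  H <- outer(hy, hx)
  Re(stats::fft(stats::fft(img) * H, inverse = TRUE)) / length(img)
}

#' Integrate an oversampled grid down to detector pixels
#'
#' Non-overlapping `os x os` block means, emulating pixel-area integration.
#'
#' @param img matrix whose dimensions are multiples of `os`
#' @param os integer oversampling factor
#' @return matrix of size `dim(img)/os`
#' @export
bin_image <- function(img, os) {
  os <- as.integer(os)
  if (os == 1L) return(img)
  nr <- nrow(img) %/% os
  nc <- ncol(img) %/% os
  stopifnot(nrow(img) == nr * os, ncol(img) == nc * os)
  dim(img) <- c(os, nr, os, nc)
  colMeans(colMeans(aperm(img, c(1, 3, 2, 4))))  # mean over the two os axes
}

#' Bilinear sampling of a matrix at displaced positions
#'
#' Returns `img` evaluated at `(y - dy, x - dx)` per pixel, i.e. the image of a
#' pattern that has been displaced by `(dx, dy)`. Out-of-range samples clamp to
#' the border.
#'
#' @param img numeric matrix
#' @param dx,dy displacement fields (matrices of `dim(img)` or scalars), in
#'   pixels of `img`
#' @return warped matrix
#' @export
warp_image <- function(img, dx, dy) {
  nr <- nrow(img); nc <- ncol(img)
  ys <- matrix(seq_len(nr), nr, nc) - dy
  xs <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - dx
  ys <- pmin(pmax(ys, 1), nr)
  xs <- pmin(pmax(xs, 1), nc)
  y0 <- pmin(floor(ys), nr - 1L); x0 <- pmin(floor(xs), nc - 1L)
  wy <- ys - y0; wx <- xs - x0
  i00 <- cbind(as.vector(y0),      as.vector(x0))
  i10 <- cbind(as.vector(y0 + 1),  as.vector(x0))
  i01 <- cbind(as.vector(y0),      as.vector(x0 + 1))
  i11 <- cbind(as.vector(y0 + 1),  as.vector(x0 + 1))
  out <- (1 - wy) * (1 - wx) * img[i00] + wy * (1 - wx) * img[i10] +
    (1 - wy) * wx * img[i01] + wy * wx * img[i11]
  matrix(out, nr, nc)
}

#' Central-difference spatial derivatives
#'
#' Second-order central differences in the interior, one-sided at the two
#' border rows/columns. The border flag lets callers down-weight those pixels.
#'
#' @param img numeric matrix
#' @return list with `dx`, `dy` (and for [laplacian_5pt()] the 5-point result)
#' @export
image_gradient <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  dx <- matrix(0, nr, nc)
  dy <- matrix(0, nr, nc)
  if (nc >= 3) {
    dx[, 2:(nc - 1)] <- (img[, 3:nc] - img[, 1:(nc - 2)]) / 2
    dx[, 1] <- img[, 2] - img[, 1]
    dx[, nc] <- img[, nc] - img[, nc - 1]
  }
  if (nr >= 3) {
    dy[2:(nr - 1), ] <- (img[3:nr, ] - img[1:(nr - 2), ]) / 2
    dy[1, ] <- img[2, ] - img[1, ]
    dy[nr, ] <- img[nr, ] - img[nr - 1, ]
  }
  list(dx = dx, dy = dy)
}

#' @rdname image_gradient
#' @export
laplacian_5pt <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  up <- img[c(1, 1:(nr - 1)), ]
  down <- img[c(2:nr, nr), ]
  left <- img[, c(1, 1:(nc - 1))]
  right <- img[, c(2:nc, nc)]
  up + down + left + right - 4 * img
}

#' Second derivatives (xx, xy, yy) by central differences
#' @keywords internal
image_hessian <- function(img) {
  g <- image_gradient(img)
  gxx <- image_gradient(g$dx)
  gyy <- image_gradient(g$dy)
  list(dxx = gxx$dx, dxy = gxx$dy, dyy = gyy$dy)
}

#' Logical mask of border pixels where one-sided stencils were used
#' @keywords internal
border_mask <- function(nr, nc, width = 1L) {
  m <- matrix(FALSE, nr, nc)
  m[seq_len(width), ] <- TRUE; m[nr + 1L - seq_len(width), ] <- TRUE
  m[, seq_len(width)] <- TRUE; m[, nc + 1L - seq_len(width)] <- TRUE
  m
}

## Deterministic per-event seed derivation (counter scheme): keeps independent
## draws reproducible and uncorrelated across pairs/realizations without
## consuming a shared RNG stream.
derive_seed <- function(seed, counter) {
  s <- (as.double(seed) * 1009 + 9973 * as.double(counter)) %% 2147483629
  as.integer(s) + 1L
}
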