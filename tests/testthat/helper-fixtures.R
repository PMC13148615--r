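# Shared fixtures: a small geometry and analytic band-limited patterns whose
# warps and blurs have closed forms (so solver tests have exact oracles).

test_geometry <- function(field = c(64L, 64L), counts = 75000) {
  acquisition_geometry(detector_shape = field, mean_counts = counts)
}

# Band-limited periodic pattern: mean `level` plus `n_modes` random-phase
# cosines with |f| <= fmax cycles/px. Returns a sampler: pattern(dx, dy,
# sigma) evaluates the pattern displaced by (dx, dy) pixels and blurred by a
# Gaussian of the given sigma (exact mode-wise attenuation). dx/dy/sigma may
# be scalars or matrices of the field size.
make_band_pattern <- function(nr, nc, n_modes = 40L, fmax = 0.06,
                              contrast = 0.18, level = 75000, seed = 1L) {
  set.seed(seed)
  ang <- stats::runif(n_modes, 0, 2 * pi)
  fr <- stats::runif(n_modes, 0.25 * fmax, fmax)
  fx <- fr * cos(ang)
  fy <- fr * sin(ang)
  ph <- stats::runif(n_modes, 0, 2 * pi)
  amp <- max(level, 1) * contrast * sqrt(2 / n_modes)
  X <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  Y <- matrix(seq_len(nr), nr, nc)
  function(dx = 0, dy = 0, sigma = 0) {
    out <- matrix(level, nr, nc)
    for (j in seq_len(n_modes)) {
      att <- exp(-2 * pi^2 * sigma^2 * (fx[j]^2 + fy[j]^2))
      out <- out + amp * att *
        cos(2 * pi * (fx[j] * (X - dx) + fy[j] * (Y - dy)) + ph[j])
    }
    out
  }
}

# Assemble a mobi_pairs object from lists of images
make_pairs <- function(Ir, Is, geometry = test_geometry(dim(Ir[[1]]))) {
  structure(list(Ir = Ir, Is = Is,
                 shifts = matrix(0L, length(Ir), 2L),
                 geometry = geometry,
                 field_px = dim(Ir[[1]]), topology = "synthetic"),
            class = "mobi_pairs")
}

# K views of a band pattern under distinct reference shifts, with the sample
# action (displacement field, transmission, blur field) applied analytically
band_pattern_pairs <- function(K = 6L, nr = 64L, nc = 64L, dx = 0, dy = 0,
                               trans = 1, sigma = 0, noise = FALSE,
                               counts = 75000, seed = 7L, fmax = 0.06) {
  pat <- make_band_pattern(nr, nc, seed = seed, level = counts, fmax = fmax)
  set.seed(seed + 1L)
  sx <- stats::runif(K, -40, 40); sy <- stats::runif(K, -40, 40)
  Ir <- lapply(seq_len(K), function(k) pat(sx[k], sy[k]))
  Is <- lapply(seq_len(K), function(k) trans * pat(sx[k] + dx, sy[k] + dy, sigma))
  if (noise) {
    for (k in seq_len(K)) {
      set.seed(seed + 10L + k)
      Ir[[k]] <- matrix(stats::rpois(nr * nc, Ir[[k]]), nr, nc)
      set.seed(seed + 10L + K + k)
      Is[[k]] <- matrix(stats::rpois(nr * nc, Is[[k]]), nr, nc)
    }
  }
  make_pairs(Ir, Is, test_geometry(c(nr, nc), counts))
}

# smooth low-frequency random field in [lo, hi] (periodic)
smooth_field <- function(nr, nc, lo, hi, seed = 1L, fmax = 0.04) {
  pat <- make_band_pattern(nr, nc, n_modes = 12L, fmax = fmax, contrast = 1,
                           level = 0, seed = seed)
  f <- pat()
  lo + (hi - lo) * (f - min(f)) / max(max(f) - min(f), 1e-12)
}
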