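#!/usr/bin/env Rscript
# Dark-field and directional dark-field on the synthetic fiber phantom
# (two orthogonal anisotropically scattering bundles + a non-scattering
# nylon wire): scalar D_f SNR and DDF saturation-SNR per topology, plus the
# HSV-encoded orientation map for the spiral mask.
# Writes: results/darkfield_snr.csv, results/ddf_spiral_rgb.tif

library(mobir)
library(tiff)
dir.create("results", showWarnings = FALSE)

geom <- xeuss_geometry(c(160L, 160L))
os <- 2L
grid <- sample_grid(geom, c(160L, 160L), os = os)
fib <- fiber_phantom(grid, sigma_px = 1.0)
height <- calibrated_cone_height(geom, 4, os = os)
bundle <- bin_image((fib$df_sigma_px$sx + fib$df_sigma_px$sy) > 0, os) > 0.5
roi_sig <- list(rows = which(rowSums(bundle) > 0),
                cols = which(colSums(bundle) > 0))
roi_bg <- list(rows = 1:12, cols = 1:60)

rows <- list()
for (topo in c("random", "hexagonal", "spiral")) {
  mask <- build_mask(topo, 4, geom, c(160L, 160L), margin_px = 160L, os = os,
                     cone_height_um = height, seed = 2L)
  p <- acquire_series(mask, fib, geom, K = 10L, seed = 9L, os = os,
                      field_px = c(160L, 160L))
  r <- lcs_retrieve(p, clip_df = TRUE)
  ddf <- directional_darkfield(p)
  rows[[topo]] <- data.frame(
    topology = topo,
    snr_df = snr(r$D_f, roi_sig, roi_bg),
    snr_ddf_saturation = snr(ddf$a, roi_sig, roi_bg))
  if (topo == "spiral") {
    writeTIFF(ddf_to_hsv(ddf), "results/ddf_spiral_rgb.tif")
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/darkfield_snr.csv", row.names = FALSE)
print(tab)
cat("\nFiber bundles light up in dark-field with orientation encoded in\n",
    "hue; the nylon wire stays dark (refraction without scattering).\n")
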