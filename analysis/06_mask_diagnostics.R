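#!/usr/bin/env Rscript
# Why do the topologies rank the way they do? Gradient-value and
# gradient-orientation distributions of the reference images (single and
# sum-of-10), and modulation packing-density maps.
# Writes: results/gradient_histograms.csv, results/orientation_entropy.csv,
#         results/packing_density.csv

library(mobir)
dir.create("results", showWarnings = FALSE)

geom <- xeuss_geometry(c(256L, 256L))
spacing <- 4
height <- calibrated_cone_height(geom, spacing)

hist_rows <- list(); ent_rows <- list(); dens_rows <- list()
for (topo in c("random", "hexagonal", "regular", "spiral")) {
  mask <- build_mask(topo, spacing, geom, c(256L, 256L), margin_px = 160L,
                     os = 4L, cone_height_um = height, seed = 1L)
  p <- acquire_series(mask, NULL, geom, K = 10L, seed = 5L, os = 4L,
                      field_px = c(256L, 256L))
  for (scope in c("single_reference", "sum_of_K")) {
    gs <- gradient_stats(p$Ir, scope = scope)
    hist_rows[[paste(topo, scope)]] <- data.frame(
      topology = topo, scope = scope,
      bin = seq_along(gs$magnitude_histogram),
      magnitude_frac = gs$magnitude_histogram)
    ent_rows[[paste(topo, scope)]] <- data.frame(
      topology = topo, scope = scope,
      orientation_entropy = gs$orientation_entropy,
      isotropy_p = orientation_isotropy_pvalue(gs))
  }
  pd <- packing_density(p$Ir[[1]], spacing_px = spacing)
  dens_rows[[topo]] <- data.frame(topology = topo, mean_density = pd$mean,
                                  sd_density = pd$sd,
                                  n_detected = pd$n_detected)
}
write.csv(do.call(rbind, hist_rows), "results/gradient_histograms.csv",
          row.names = FALSE)
write.csv(do.call(rbind, ent_rows), "results/orientation_entropy.csv",
          row.names = FALSE)
write.csv(do.call(rbind, dens_rows), "results/packing_density.csv",
          row.names = FALSE)
print(do.call(rbind, ent_rows))
print(do.call(rbind, dens_rows))
cat("\nRandom and spiral gradients are isotropic (high entropy); lattices\n",
    "concentrate on preferred axes — reinforced on the summed stack. The\n",
    "random pattern paves the field sparsely and unevenly (low mean, high\n",
    "sd); the spiral keeps lattice-like density with isotropy.\n")
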