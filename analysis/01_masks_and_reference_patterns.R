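#!/usr/bin/env Rscript
# Build the four membrane topologies at the design spacing, calibrate the
# common cone height, and record each mask's reference-image statistics.
# Writes: results/mask_gallery/  (mask TIFFs + JSON sidecars)
#         results/reference_stats.csv

library(mobir)

out_dir <- "results"
dir.create(file.path(out_dir, "mask_gallery"), recursive = TRUE,
           showWarnings = FALSE)

geom <- xeuss_geometry(c(256L, 256L))
spacing <- 4   # detector px, inside the 3-6 px optimum
height <- calibrated_cone_height(geom, spacing)
cat(sprintf("calibrated cone height: %.1f um (spiral visibility 15%%)\n", height))

rows <- list()
for (topo in c("random", "hexagonal", "regular", "spiral")) {
  mask <- build_mask(topo, spacing, geom, c(256L, 256L), margin_px = 16L,
                     os = 4L, cone_height_um = height, seed = 1L)
  write_mask(mask, file.path(out_dir, "mask_gallery", paste0(topo, ".tif")))
  I <- bin_image(reference_intensity(mask, geom, os = 4L), 4L)
  gr <- image_gradient(I)
  rows[[topo]] <- data.frame(
    topology = topo,
    visibility = sd(I) / mean(I),
    mean_counts = mean(I),
    grad_rms = sqrt(mean(gr$dx^2 + gr$dy^2)),
    orientation_entropy = gradient_stats(I)$orientation_entropy)
  cat(sprintf("%-10s visibility %.3f  |grad| rms %.0f counts/px\n",
              topo, rows[[topo]]$visibility, rows[[topo]]$grad_rms))
}
tab <- do.call(rbind, rows)
write.csv(tab, file.path(out_dir, "reference_stats.csv"), row.names = FALSE)
cat("The quasi-random patterns (random, spiral) carry near-isotropic\n",
    "gradient content; the lattices concentrate theirs on a few axes.\n")
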