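# mobir — modulation-based X-ray phase-contrast and dark-field imaging

Single-mask (modulation-based) X-ray imaging inserts one membrane into the
beam to imprint an intensity pattern on the detector; the distortions a
sample causes in that pattern encode its absorption, refraction and
small-angle scattering. `mobir` is an R toolkit for the question *which
membrane topology retrieves the best images*: it generates
structured-illumination masks of four topologies (random/sandpaper-like,
hexagonal honeycomb, square grid, Vogel spiral), simulates reference/sample
detector image pairs for parametric nylon phantoms in a cone-beam
laboratory geometry (75 µm pixels, 8.6 keV, 75 000 counts/pixel, Poisson
noise), retrieves the sample signals, and scores the result with standard
image-quality metrics and mask diagnostics.

The retrieval is an implicit per-pixel least-squares system built on
transport-of-intensity and optical-flow conservation. For membrane position
$k$:

$$ I_{r,k} - I_{s,k} = I_\mathrm{obj} I_{r,k}
   + D_x \partial_x I_{r,k} + D_y \partial_y I_{r,k}
   - D_f \nabla^2 I_{r,k} $$

with per-pixel unknowns: attenuation sink $I_\mathrm{obj}$, pattern
displacement $(D_x, D_y)$ in detector pixels (refraction angle
$\alpha = D\,p/z_2$; the phase is the least-squares integral of the angle
gradient), and a Laplacian-coupled dark-field diffusion term $D_f$
($\approx \sigma^2/2$ for a local blur $\sigma$). $K \ge 4$ membrane
positions determine the four unknowns; with $K \ge 6$ a symmetric 2×2
scattering tensor replaces $D_f$ and yields directional dark-field
(orientation/anisotropy, HSV-encoded). Quality metrics: NRMSE against the
theoretical displacement $D_{0y} = z_2 \nabla(\delta t)/p$, the SSIM family
(SSIM, MS-SSIM, SR-SIM, VSI), Fourier ring correlation between independent
realizations (resolution at the 1/7 crossing), angular sensitivity in
sample-free windows, and ROI SNR for dark-field.

The methods vignette (`vignettes/mask-topology-methods.Rmd`) documents the
models, every fixed convention, and the measured limits of the simulation.

## Worked example

Simulate ten shifted reference/sample pairs of a fractal relief phantom
behind a Vogel-spiral membrane, retrieve, and score:

```r
library(mobir)

geom <- xeuss_geometry(c(256L, 256L))          # 0.33/0.55/1.35 m, 75 um px
height <- calibrated_cone_height(geom, 4)      # one cone height for all masks
grid <- sample_grid(geom, c(256L, 256L), os = 4L)
fractal <- study_phantom("julia", grid, geom)

run <- run_retrieval("spiral", fractal, geom, spacing_px = 4,
                     cone_height_um = height, K = 10L, shift_axes = "x",
                     field_px = c(256L, 256L), seed = 5)
D0 <- theoretical_displacement(fractal, geom, os = 4L)
nrmse(run$retrieval$D_y, D0$D0_y)
#> [1] 0.6765
ssim(run$retrieval$D_y, D0$D0_y)
#> [1] 0.817
```

The NRMSE of 0.68 against the ideal displacement map (and SSIM 0.82) is the
spiral membrane's score on this scene; re-running with
`"random"` / `"hexagonal"` / `"regular"` gives 0.74 / 4.00 / 5.96 —
the quasi-periodic spiral retrieves best, and the axis-aligned square grid
fails through periodicity artifacts under single-axis membrane shifts,
exactly the behaviour the packaged experiments quantify.

The numbered scripts under `analysis/` run the full study at desk scale and
write their tables to `results/`: mask gallery and reference statistics
(01), the NRMSE-vs-modulation-size sweep (02), the six-phantom topology
comparison (03), FRC resolutions (04), the angular-sensitivity table (05),
gradient/packing-density diagnostics (06), and the synthetic fiber-phantom
dark-field comparison (07).

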