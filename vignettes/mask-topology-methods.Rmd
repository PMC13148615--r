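---
title: "Membrane topology for modulation-based X-ray imaging: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane topology for modulation-based X-ray imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mobir` simulates single-mask (modulation-based) X-ray phase-contrast and
dark-field imaging and retrieves the sample signals with an implicit
per-pixel least-squares system. This vignette is the package's own account
of the models it implements, the conventions it fixes where the physics or
the literature leaves a choice open, and what its synthetic experiments can
and cannot show about real instruments.

## The imaging model

A membrane ("mask") carrying many small modulators imprints an intensity
pattern $I_r$ on the detector. Introducing a sample multiplies the pattern
by its transmission, displaces it by refraction, and washes it out locally
through small-angle scattering. For each membrane position $k$ and each
pixel, the package linearizes this interplay as

$$ I_{r,k} - I_{s,k} \;=\; I_\mathrm{obj}\, I_{r,k}
   + D_x\, \partial_x I_{r,k} + D_y\, \partial_y I_{r,k}
   - D_f\, \nabla^2 I_{r,k}, $$

a transport-of-intensity / optical-flow conservation form with four unknown
per-pixel fields: an attenuation sink $I_\mathrm{obj}$, the transverse
pattern displacement $(D_x, D_y)$ in detector pixels, and a diffusion
(dark-field) term $D_f$. A Gaussian blur of width $\sigma$ adds
$\tfrac{\sigma^2}{2}\nabla^2 I_r$ to first order, so blurring samples give
$D_f \approx \sigma^2/2 \ge 0$ with the sign convention above. With $K \ge 4$
membrane positions the per-pixel system is solved by Tikhonov-damped least
squares (`solve_lcs()`); with $K \ge 6$ a symmetric $2\times 2$ scattering
tensor replaces $D_f$ (`directional_darkfield()`), giving orientation and
anisotropy of the scattering structures (HSV-encoded as in dark-field
practice: hue = principal-axis angle mod $\pi$, saturation = principal
semi-axis, value = tensor norm).

Displacements convert to refraction angles as
$\alpha = D\,p/z_2$ ($p$ = 75 µm pixel, $z_2$ = 0.80 m sample-detector
distance; 1 px = 93.75 µrad), and the phase is the Frankot–Chellappa
least-squares integral of the angle gradient (`integrate_phase()`), reported
zero-mean.

Key numerical conventions, fixed and documented here because the linearized
form admits sign/placement freedom:

* rows are $[I_r, \partial_x I_r, \partial_y I_r, -\nabla^2 I_r]$ with
  right-hand side $I_r - I_s$; positive $I_\mathrm{obj}$ = attenuation,
  positive $D_f$ = blur;
* derivatives are 2nd-order central differences (5-point Laplacian),
  one-sided at image borders (border pixels flagged);
* the damping $\lambda$ (default $10^{-3}$) is scaled per column by the
  column's mean square, so it is one dimensionless knob; rank-deficient
  pixels fall back to the minimum-norm solution, are counted, and are
  inpainted from neighbours;
* `solve_lcs(pool_w = w)` optionally pools the equations of a $w\times w$
  neighbourhood (a robustness knob); the default $w = 1$ is the plain
  per-pixel method and is used everywhere in the reported experiments.

Because the derivative stencils act on a sampled pattern, retrieved
displacements carry a frequency-dependent scale factor
$2\pi f/\sin(2\pi f)$ relative to the continuum; at the 3–6 px modulation
sizes this is a 10–30 % overestimate. It affects all topologies alike and
cancels from orderings, FRC resolutions and sensitivity comparisons.

## Geometry and optical constants

The cone-beam geometry follows the laboratory instrument the study targets:
source–membrane 0.33 m, source–sample 0.55 m, sample–detector 0.80 m, 75 µm
pixels, 8.6 keV mean energy (treated as monochromatic; full polychromatic
spectra are out of scope), 50 µm source spot, and a mean of 75 000 counts
per detector pixel *on the detector*, i.e. after mask transmission, with
Poisson noise. Magnifications are plane-wise ($M = d_\mathrm{tot}/d$),
source blur is the penumbral Gaussian FWHM $= 50\,\mu m\,(M-1)$ applied to
the membrane pattern (blur placement before the sample is the default; it is
a configuration choice), and the Fresnel cross-check propagates over the
cone-beam effective distance $z_2/M_\mathrm{sample}$.

δ and µ at 8.6 keV for nylon, SiO₂, Ni and resin are shipped as a versioned
in-code table (classical $r_e\lambda^2 n_e/2\pi$ for δ, elemental mass
attenuation combined by mass fraction for µ). Only internal consistency
matters for the quality metrics, since the forward model and the theoretical
displacement maps use the same constants.

## Membrane construction

Four point-pattern topologies generate the membranes: uniform random with a
hard core (sandpaper grains), triangular/honeycomb lattice, square grid, and
the Vogel spiral $r = c\sqrt{k}$, $\theta = k \times 137.50776^\circ$ (golden
angle, $k = 0$ at the center) — the sunflower pattern that paves the plane
quasi-uniformly with no preferred direction. Points are rasterized as SiO₂
cones (height at apex, linear taper; overlaps sum) or as drilled holes in a
Ni plate.

Conventions the package fixes, chosen once on physical grounds:

* **Design spacing.** The swept "peak-to-peak modulation size" is the
  lattice pitch (hexagonal, square), the density-matched Vogel scale
  $c = s/\sqrt{\pi}$, and — for the random pattern — the *mean
  nearest-neighbour distance*, obtained by solving the hard-core mean-NN
  relation for the point density. The random membrane is therefore sparser
  than the structured ones at equal design spacing, which is exactly its
  measured weakness (packing-density analysis below).
* **Modulator size.** Dots of diameter $0.7 s$ for every topology — the
  ratio of the drilled experimental masks (60 µm holes at a few-pixel
  design spacing). The random topology draws diameters ±20 % (graded grit)
  and uses a hard core of $0.6 s$ (a single layer of grains, side by side).
* **Whole-micrometre fabrication.** Pitches and diameters are rounded to
  integer micrometres at the membrane plane. A mask specified as an exact
  integer number of detector pixels would be commensurate with the
  integer-pixel shift protocol — only a handful of distinct lattice phases
  in ten shifts — a degeneracy no fabricated mask has.
* **Amplitude calibration.** The study fixes one cone height for all
  topologies and sizes. The printed nominal height (200 nm of SiO₂) yields
  ~10⁻⁴ absorption contrast at 8.6 keV, far below any usable modulation, so
  the default height is calibrated once so that the spiral mask at the
  design spacing reaches a noise-free reference visibility (std/mean) of
  0.15, the middle of the 5–20 % band a usable modulation occupies; the
  nominal value remains available (`build_mask(..., cone_height_um =)`).
  Calibration is monotone bisection (`calibrate_mask_visibility()`).

Lattices are axis-aligned (their canonical construction). Under the
one-motor protocol (shifts along $x$ only) this makes the honeycomb's rows
stationary in $y$ — the mechanism behind its order-of-magnitude worse
vertical angular sensitivity — and gives the square grid its periodicity
artifacts.

## Phantoms and desk-scale conditions

Six nylon phantoms (wire ∅1.5 mm — horizontal, so its refraction lives in
$D_y$; sphere ∅12 mm; cube 7 mm; torus 13/3/3 mm; a Shepp–Logan ellipse
stack 13 × 18 mm with 1–5 mm thickness; a Julia-set escape-time relief
18 × 10 mm, max 5 mm) are rendered as projected-thickness maps on the
detector-conjugate sample grid.

The reported experiments run at desk scale (256–512 px fields rather than
the full 514 × 1030 detector). `study_phantom()` keeps the scene
composition by scaling transverse dimensions with the field (relative to
the full detector height), capping the footprint at 85 % of the field so a
sample-free border exists for the sensitivity windows; projected
thicknesses keep their design values. All study phantoms are rendered with
a 60 µm Gaussian edge rounding — the fabrication resolution of printed or
machined phantoms. This matters: a mathematically sharp edge has unbounded
thickness gradient, i.e. a theoretical displacement of several pixels in a
single-pixel-wide sliver, which no small-displacement retrieval can
represent; without the rounding, every topology's NRMSE is dominated by the
same unrecoverable cliff spikes and the comparison degenerates.

## Quality metrics

All indices operate on displacement maps (phase maps are rejected by type):
NRMSE against the theoretical map $D_{0y} = z_2\,\nabla(\delta t)/p$;
SSIM (uniform 7 × 7 window, $k_1 = 0.01$, $k_2 = 0.03$, $L$ = joint dynamic
range); MS-SSIM (5 dyadic scales, standard weights); SR-SIM and a grayscale
VSI (spectral-residual saliency, published stabilizers, maps rescaled to an
8-bit range first — both parameter sets are frozen conventions, since the
study names but does not parameterize them); FRC between two independent
realizations (one-bin rings, no apodization by default, resolution $1/f$ at
the first 1/7 crossing by linear interpolation, Nyquist floor flagged when
no crossing); angular sensitivity as the std of $\alpha_y$ over eight
5 × 40 px windows auto-placed on the outermost sample-free border tiles;
and ROI SNR for dark-field maps.

## What the simulations do and do not show

The generator reproduces the stated acquisition conditions: 10
reference/sample pairs, integer membrane shifts of 50–150 px along one or
two axes (each pair's shift recorded), Poisson noise at 75 000 counts, the
cone-beam geometry above. It does not model polychromaticity, detector
point-spread or charge sharing, vacuum-chamber scatter, or any
sample-microstructure scattering — the study itself validates dark-field
only on measured data, and the fiber phantom here (`fiber_phantom()`) is a
labelled synthetic stand-in whose anisotropic blur exercises the tensor
retrieval rather than reproducing a measurement.

Two quantitative consequences, measured and worth stating plainly:

* **Orderings reproduce; absolute noise floors do not.** With per-pixel
  solving at 75 000 counts and $K = 10$, the displacement noise floor is
  bounded below by $\sqrt{2N}/(\sqrt{K}\,\mathrm{rms}\,\partial I_r)$ —
  about $2\times 10^{-2}$ px here, i.e. a vertical angular sensitivity of
  order 1500–4000 nrad (spiral < random) and ~20 000 nrad for the
  honeycomb. The study's published table reports 98/141/810 nrad — the same
  ordering at roughly 17× smaller magnitude, which per-pixel estimation at
  these photon statistics cannot reach (it would need ~10⁻³ px per pixel).
  The published pipeline plausibly pools or filters; the `pool_w` knob
  reproduces that direction of improvement but is off by default, because
  the per-pixel method is the documented baseline. FRC resolutions shift
  accordingly (spiral ≈ 4.7 px here vs 2.3 px published, same best-to-worst
  direction for the quasi-random patterns).
* **The diffusion term has a Poisson floor.** Per-pixel $D_f$ carries an
  error floor of ~0.05–0.1 px² at this count level, so smooth blur fields
  are recovered to ~20 % of their range where the displacement and
  absorption fields reach 3–7 %.

## Reported problem sizes

The packaged experiments use a 256 × 256 px field for the modulation-size
sweep and the six-phantom comparison, 512 × 512 px for FRC, and
256 × 320 px for the sensitivity table, all with $K = 10$ pairs and the
full-count noise level; the analysis scripts under `analysis/` regenerate
every table in `results/` from these protocols with fixed seeds.

## Known limitations

* Monochromatic forward model; spectral weighting is a few-line extension
  but is not exercised by the reported experiments.
* The warp model treats refraction ray-optically; the Fresnel path agrees
  with it to ~10 % on gentle gratings (tested) but free-space fringe
  contrast of sharp modulators is only represented through the source blur.
* Per-pixel retrieval inherits the stencil scale bias and the noise floors
  quantified above; tensor dark-field needs $K \ge 6$ and clips non-PSD
  pixels (counted, reported).
* The random-membrane model is a hard-core monolayer; layered sandpaper
  stacks (multiple grain sheets) are out of scope.
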