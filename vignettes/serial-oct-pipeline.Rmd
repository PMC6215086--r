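---
title: "Methods: dual-resolution serial OCT reconstruction and OCT-dMRI comparison"
author: "serialoct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-resolution serial OCT reconstruction and OCT-dMRI comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`serialoct` implements the computational side of a dual-resolution serial
blockface OCT scanner for whole mouse brains: a low-magnification arm images
and mosaics the entire block face slice by slice while a high-magnification
arm revisits automatically selected regions of interest (ROIs), and the
assembled brain is carried through affine transforms into diffusion-MRI
space for multimodal comparison. Because the instrument itself cannot ship
with a package, a seeded digital phantom and forward simulators for fringes
and diffusion-weighted series stand in for the hardware; every stage of the
pipeline is exercised against ground truth it can be held to.

This vignette records the models, the conventions, the tunable parameters
and the design decisions, in the package's own words. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

# Coordinate and unit conventions

* `x`, `y` are lateral stage-plane coordinates; `z` is depth into the
  tissue. All physical lengths are micrometres (um) unless a name says
  otherwise; attenuation is mm^-1 and b-values are s/mm^2.
* Pixel/voxel centers sit at `(i - 0.5) * spacing` from the grid origin
  (0-based physical frames, half-open extents); resampling of intensities
  is linear, of labels nearest-neighbour.
* Fringes are sampled linearly in wavenumber `k = 2*pi/lambda`. A reflector
  at depth `z` in a medium of index `n` (water, 1.33) contributes
  `sqrt(I) * cos(2 k n z)`, so the reconstructed depth-bin spacing is
  `dz = pi / ((k_max - k_min) * n)` — about 6.44 um for the default
  1310 +- 50 nm sweep with 256 k-samples.

# Fringe model and reconstruction

Reconstruction (`reconstruct_aline`, `reconstruct_tile`) follows the
acquisition pipeline: subtract the reference fringe (the tile-average
fringe, computed from the data), multiply by a Gaussian spectral apodization
window (mu = 1310 nm, sigma = 20 nm, expressed in wavelength and resampled
onto the k-grid, peak-normalized), inverse Fourier transform, and keep the
first half of the axial range — the second half duplicates it because real
signals have Hermitian spectra. Magnitudes are squared to intensity and
scaled so a unit-amplitude cosine reconstructs to unit intensity.

The simulator (`simulate_tile_fringes`) inverts this: the ground-truth depth
profile `I(z) = reflectivity * T(z) * exp(-2 \int mu dz)` is evaluated on
the reconstruction depth bins and a real fringe is synthesized as a sum of
cosines with amplitudes `sqrt(I)`. Two phase choices matter and are worth
recording:

* **Depth-phase reference.** The cosine for depth bin `l` carries a
  `(-1)^l` factor, i.e. the depth phase is referenced to the centre of the
  spectral window rather than to the lowest sampled wavenumber (a
  half-sample shift of the k origin). Reconstructed magnitudes are
  identical either way, but with the window applied the window's transform
  alternates sign across depth bins; without this referencing, coherent
  neighbouring bins of a smooth profile partially cancel instead of being
  gently blurred. With it, apodization acts as the expected small axial
  smoothing.
* **Per-A-line phase diversity.** Each A-line carries a global phase from a
  deterministic golden-angle sequence over the lateral raster. This leaves
  every reconstructed magnitude untouched while making the tile-average
  fringe negligible, which is what lets the data-derived reference
  subtraction isolate common-mode signal, as it does in practice where
  lateral speckle decorrelates A-lines. `phase_mode = "zero"` gives fully
  coherent fringes (useful for algebraic checks), `"speckle"` draws
  independent per-bin phases — a crude speckle switch, intentionally not a
  statistical speckle model.

The digitizer's 12-bit quantization is available (`quantize_12bit`) and off
by default; tests run unquantized.

**Axial PSF.** `measure_axial_psf_fwhm()` reconstructs a simulated mirror
through the apodized pipeline and measures the full width at half maximum of
the intensity peak; with the default sweep it reports about 8.9 um in water.
The nominal system description quotes 7.5 um for this window; the standard
Gaussian-spectrum relation for sigma = 20 nm gives a larger figure, so the
package reports the width it actually measures rather than pinning either
number.

# Attenuation estimation and depth compensation

Depth-dependent contrast follows the single-scattering model combined with
the confocal axial point-spread envelope:

$$ I(z) = i_0 \; T(z) \; e^{-2\mu (z - z_s)}, \qquad
   T(z) = \left[\left(\tfrac{z - z_f}{z_r}\right)^2 + 1\right]^{-1} $$

with `z_s` the tissue surface, `z_f` the focal depth and `z_r` the apparent
Rayleigh range (the low-magnification arm has a long depth of focus;
1000 um is the working default). `fit_attenuation` fits `log I - log T`
linearly in depth per A-line — the log domain keeps the problem linear and
robust — with two numerical safeguards: voxels below `mask_rel` times the
volume maximum are excluded, and samples are weighted by intensity squared,
since `var(log(I + noise)) ~ (sd/I)^2`; without the weighting the
low-signal tail biases mu downward by several percent at realistic noise.
A-lines with fewer than 16 usable samples (or all-zero) are flagged invalid
and excluded from the tile median rather than raising an error.
`compensate_depth` divides by `T(z) exp(-2 mu (z - z_s))` at and below the
surface only, using per-A-line estimates where valid and the tile median
elsewhere; a second fit on compensated data returns mu near zero.

# Mosaicking and whole-brain assembly

Tiles are placed by their **recorded stage positions** — no pairwise
registration — which requires the stage model `p = A pM + b`
(`calibrate_stage`): a least-squares fit from commanded microsteps to the
translations measured by `phase_correlation` between images taken at each
position. Collinear calibration displacements are rejected as
rank-deficient.

Blending (`blend_weights`) is feathering by normalized distance to each
tile's own boundary: continuous, 1 deep inside a tile's exclusive zone, 0 at
its edge, and normalized so that the tiles covering any pixel sum to exactly
one — the steady state of the diffusion-style construction that the
acquisition literature names without specifying. An iterative heat-kernel
variant (`method = "heat"`, Gaussian-smoothed footprint indicators) is
provided to cross-validate the default; both are partitions of unity.
Stitching constant tiles yields a constant mosaic to within 1e-6, and tiles
cut from one image reassemble it exactly on covered pixels.

Slices are assembled at 25 um isotropic (`assemble_brain`); the roughly
100 um of axial overlap between consecutive 200 um slices is blended with
the same 1-D feathering, normalized across slices. The slice AIP averages
the first 800 um of depth — the depth range the low-magnification volumes
usefully contain.

`polygon_to_tiles` covers a closed polygon with the minimal axis-aligned
grid of 0.5 mm tiles at 20% overlap (stride 0.4 mm); grid size is the
ceiling of the covered span over the stride, so a 1.3 x 0.5 mm rectangle
needs 3 x 1 tiles.

# Autofocus and the focal surface

The autofocus metric is the mean intensity of the central A-line
(`focus_metric`; linear intensity — the acquisition does not state a log
variant, and linear keeps the metric proportional to backscattered power).
`fibonacci_search` is the classical Fibonacci elimination for a unimodal
maximum: after `n` evaluations the bracket has length `(b - a)/F(n+1)`
exactly (the final evaluation is the standard epsilon probe that resolves
the degenerate midpoint comparison), and the returned depth is the final
bracket's midpoint.

The water/tissue interface is found per lateral position by convolving the
axial profile with the first derivative of a Gaussian and taking the depth
of maximum response (`detect_interface_depth`). Edge polarity is fixed to
rising — water is darker than tissue ex vivo — and configurable; the scale
defaults to one coarse scan step (50 um) since no value is stated for it. A
response below 5% of the profile's dynamic range means "no interface", which
per-position failures turn into mask entries rather than errors
(`interface_surface`).

The interface surface is summarized by least squares onto ANSI/OSA
single-index Zernike polynomials Z0..Z5 (piston, vertical tilt, horizontal
tilt, oblique astigmatism, defocus, vertical astigmatism; orthonormal on the
unit disk, with the surface mapped so the farthest valid pixel sits on the
disk edge). The decomposition is an exact linear projection on that span —
planted coefficients, including the defocus amplitudes typical of this
optical design (|c4| around 0.26), are recovered to 1e-6.

# Automated ROI selection

`segment_tissue` denoises the slice AIP with a bilateral filter (spatial
sigma 3 px, range sigma 0.1 of the dynamic range; hand-written since no
installed package provides one), thresholds with Otsu (tissue = bright
class), despeckles with a median filter and fills holes. The probability
bias map (`probability_map`) is

$$ f = \mathrm{norm01}(\mathrm{AIP}) +
       \mathrm{norm01}\left(|\mathrm{AIP} - \overline{\mathrm{AIP}}_{mask}|\right) $$

Gaussian-smoothed with sigma = 75 um ("kernel size 75 um" is read as the
Gaussian sigma, not FWHM — configurable), zeroed outside the mask, and
normalized to unit mass over it. Smoothing happens before masking (the
alternative order is not stated anywhere; this one keeps the map's support
exactly inside the mask). `norm01` is min-max over the mask; a degenerate
(constant) feature map falls back to uniform. Both features being min-max
normalized makes the map invariant to affine intensity rescaling of the
AIP.

`sample_rois` draws centers without replacement, weighted by the map, from
the mask eroded by the 250 um agarose margin (Euclidean distance
transform), rejecting candidates closer than `min_separation_um`
(center-to-center; the overlap-style variant is the same constraint with
`fov - separation`) to an accepted ROI; rejection is capped at `100 n`
attempts before declaring the constraints infeasible. Selection runs every
fourth slice (`schedule_rois`). Sampling is bit-reproducible given the
seed.

# ROI mapping and structure bookkeeping

`match_template` relocates a high-resolution ROI inside the assembled slice
by zero-mean normalized cross-correlation at the 25 um/px working
resolution, computed for every placement via FFT cross-correlation plus
summed-area tables — numerically identical to the brute-force loop, which
the tests also run. The search window defaults to +-1 mm around the
commanded position, comfortably covering the stage's measured
repeatability. `build_overlay` rasterizes each ROI as an axis-aligned
labeled block (0.5 mm across 20 voxels at 25 um) at its registered
position; colliding blocks resolve last-writer-wins with a logged warning.
`apply_affine` composes the given 4x4 transforms (registration estimation
is out of scope; transforms are inputs) and pulls labels back through the
inverse by nearest neighbour, so no labels are invented. Structure volume
fractions and the fiber-tract flag come from the atlas histogram under each
block; per-ROI metric means are NaN-aware.

# Diffusion MRI: scheme, drift, NuFO

The default gradient scheme is the 70-volume ex vivo protocol — 6
directions at b = 400, 15 at b = 1066, 42 at b = 2000 s/mm^2, 7 b = 0
volumes interlaced evenly. Directions are a seeded, randomly rotated
Fibonacci-sphere construction per shell: deterministic and quasi-uniform.
The electrostatic-repulsion multishell design used on the instrument is not
reimplemented — no stage of this package exercises direction optimality.
The stated 16 x 12 x 8 mm field of view over a 128 x 96 x 64 matrix gives
125 um isotropic voxels (`isotropic_voxel_size_um`).

Ex vivo samples warm toward room temperature during the 48 h acquisition,
so water diffusivity — and with it the signal — drifts. The compensation
exploits the isotropy of CSF: `estimate_drift` averages the signal over
1000 random ventricle voxels per volume, builds the synthetic multishell
isotropic profile (per-shell mean, constant within each shell), and calls
the difference the drift, smoothed temporally with a Gaussian of sigma = 1
volume. Three choices deserve a note:

* **Sign convention.** The drift is measured-minus-synthetic and is
  *subtracted* from every voxel; the corrected per-shell CSF means are then
  flat. (The alternative reading — adding the negative bias — is the same
  operation; a multiplicative variant sits behind `mode =
  "multiplicative"`.)
* **Per-shell smoothing.** The drift excess is scaled by each shell's CSF
  signal amplitude, and b = 0 differs from b = 2000 by a factor of ~50
  here; smoothing across shell boundaries would mix values on those very
  different scales and inject bias far larger than the drift itself. The
  Gaussian filter therefore runs within each shell along acquisition index
  (`per_shell = TRUE`; `FALSE` gives the plain filter).
* **Identifiability.** The measured-minus-synthetic construction is blind
  to any per-shell constant: what is recoverable is the injected drift
  minus its per-shell mean, scaled by the per-shell CSF amplitude. Recovery
  tests compare against exactly that quantity; with smoothing disabled the
  noiseless recovery is exact to machine precision.

`segment_ventricles` thresholds the b0 volume at an intensity quantile
(default 0.99 within the brain mask — roughly the fluid fraction of a mouse
brain). The package's phantom has a deliberately small ventricle (about
0.5% of the brain), so phantom-based checks pass the quantile matching the
phantom's own documented fluid fraction rather than the default.

NuFO applies the data-driven rule: threshold = 1.5 x the mean ventricle
AFD_max, NuFO = number of fODF peaks at or above it. Tensor/fODF/NODDI
fitting itself is left to the established diffusion tools whose output maps
this package consumes; the NODDI configuration used for those maps
(d_iso = 1.0e-3 mm^2/s, d_par = 0.6e-3 mm^2/s, lambda1 = 0.5,
lambda2 = 1.0e-3, ex vivo compartment) is recorded as metadata only.

# Multimodal comparison

Per-ROI OCM features are the mean and population standard deviation of the
normalized reflectivity and of the attenuation coefficient; reflectivity is
normalized by the 99.9th percentile of all ROI AIP intensities in the brain
(`reflectivity_norm_reference`) and clipped to [0, 1] — the acquisition
does not define the normalization, and an upper percentile is robust to hot
pixels. Population (divisor n) standard deviations keep the two-valued
closed forms exact.

ROIs intersecting fiber-tract structures are split at the 25/50/75% sample
quantiles of each dMRI metric (linear interpolation between order
statistics, R type 7 — membership near a cut depends on this, hence it is
pinned); Q1 and Q4 are compared per feature by a two-sample t-test. Welch's
unequal-variance form is the default — group variances have no reason to
match — with the classical pooled test behind `pooled = TRUE`. With 4
features and 5 metrics, significance is declared at 0.05/20 = 0.0025. Q2/Q3
ROIs are retained in all outputs but enter no test.

# The phantom: what it emulates, and what it does not

`make_phantom` builds an ellipsoidal brain in an agarose shell with layered
cortical reflectivity, two bright fiber ribbons crossing at the midline,
dark tubular vessels, one dark fluid ventricle, and a toy atlas (four
gray-matter quadrants, a ventricle label, two ribbon labels flagged as the
fiber-tract subset). Optical attenuation is 1.2 mm^-1 in gray matter,
5 mm^-1 in fiber bundles, 0.3 in agarose and near zero in fluid — plausible
ex vivo values chosen once (no quantitative tissue optics are stated for
the instrument). The DWI simulator uses 2.0e-3 mm^2/s for free fluid,
0.4e-3 isotropic in gray matter and a 1.0/0.15e-3 tensor along each
ribbon, mixing both populations in the crossing; ventricles are 3x brighter
at b = 0. The acceptance-level noise condition is SNR 20 at tissue b0
(`noise_sd = 0.05`), a realistic figure for 125 um ex vivo imaging.

Problem sizes are chosen for desk-scale completeness, not realism: a
64 x 64 x 32 voxel phantom at 25 um, three 200 um slices with ~100 um
overlap, 3 x 3 tile rasters of 0.5 mm tiles at 20% overlap, 256 k-samples
per fringe, and the full 70-volume scheme.

What the phantom does **not** model — and hence what passing tests cannot
show about real data: speckle statistics and phase noise, dispersion and
sensitivity roll-off, time-varying illumination/shading from debris on the
immersion window, real registration error between modalities (transforms
are exact inputs here), Rician noise and eddy/field artifacts in the dMRI,
and the anatomical complexity that makes real tissue segmentation hard.
The multimodal comparison stage is validated for its statistics (type-I
behaviour at the corrected threshold, directional effects built into the
phantom), not for reproducing any particular effect size measured on real
brains.

# Known limitations

* Dynamic-focus fusion replaces the published Gabor-domain method with
  Gaussian depth weighting (sigma = half the focal-plane spacing,
  normalized to a partition of unity): the published approach needs modeled
  defocus kernels that are not available here. With two planes one step
  apart the in-focus plane's weight is `1/(1 + e^{-2})` (about 0.88) at its
  own focus — dominant, though not overwhelmingly so; a smaller sigma
  sharpens it at the cost of visible seams on real data.
* The attenuation fit assumes one mu per A-line; layered tissue returns a
  depth-weighted compromise.
* The interface detector reports the sample of maximum response without
  subsample refinement; its resolution is the scan step.
* `apply_affine` is nearest-neighbour by design (labels), so thin blocks
  lose up to a voxel per face on resampling; the round-trip Dice floor in
  the tests (0.95) is that quantization, not registration error.
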