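---
title: "Quantifying posterior fundus shape: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying posterior fundus shape: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octmap)
```

`octmap` turns a 12-line radial OCT scan set into per-eye shape indices and an
en-face curvature topography of the Bruch's membrane (BM). This vignette is
the package's own account of the method: the model and its assumptions, the
parameters that matter, what the synthetic phantoms do and do not emulate, and
the choices made where the design was genuinely open.

## The shape model

The BM line is used as the fundus-shape proxy because retinal and RPE surfaces
are easily distorted by neovascular membranes, schisis cavities and atrophy,
while the BM stays comparatively smooth. Shape is summarised by *signed local
curvature*: along each scan line, with the boundary expressed as depth
`f(x)` in micrometres (posterior-positive) against transverse position `x`,

$$\kappa(x) = \frac{f''(x)}{\left(1 + f'(x)^2\right)^{3/2}},$$

with both derivatives taken by central differences over three samples spaced
`h = 500` µm — the radial A-scan spacing — so each κ describes shape over a
1000-µm window. Working with *local* curvature rather than a global sphere
fit is what lets the map pick up small undulations and the inflection at a
staphyloma edge; it is also what makes the measure insensitive to the overall
geometric distortion of OCT images (a global tilt or stretch changes local
curvature little over a 1-mm window).

Two statements fix the sign convention: κ is positive where the membrane is
convex toward the vitreous, and depth is posterior-positive. A normal
(spherical, R ≈ 13 mm) posterior pole then has constant small negative
curvature −1/R ≈ −7.7×10⁻⁵ 1/µm, a staphyloma floor is strongly negative, and
the staphyloma edge — which must contain an inflection — carries a
zero-to-positive ring. Collinear samples give exactly κ = 0. (Verbal
descriptions of this convention in the source literature are mutually
inconsistent between "convex upward" and "upward concave"; the convention
here is the one consistent with all of the qualitative map descriptions:
negative normal pole, red/negative staphyloma floor, green/positive edge
ring.)

### Evaluation grid vs. stencil

Curvature is *evaluated* on a dense 1-µm grid (linear interpolation of the
traced boundary), while the stencil arms stay fixed at 500 µm. The dense
evaluation makes the per-eye statistics insensitive to grid phase; the fixed
arms keep the 1000-µm physical support of each estimate. No evaluation is
made within 500 µm of a trace end or of an invalid span, which trims a 9-mm
line to an 8-mm evaluated extent. Interpolation is deliberately linear and
unsmoothed — smoothing is the active contour's job, and doing it twice would
bias curvature magnitudes down.

## Segmentation

Per B-scan, working on the median-filtered image (3×3 window by default):

1. a **layer-structure filter** — the rectified negative axial second
   derivative of a Gaussian-smoothed image (axial scale 2 px, lateral 1 px) —
   responds to bright, roughly horizontal bands;
2. per A-scan column, the **first** depth peak of that response at or above a
   threshold seeds the inner boundaries, and the **last** such peak seeds the
   BM; the threshold defaults to 0.3 of the image-wide maximum response,
   which is scale-free across 8- and 16-bit inputs;
3. each seed is refined to the nearest signed **Sobel** depth-gradient peak:
   anteriorly (rising gradient) for the ILM, posteriorly (falling gradient)
   for the nerve-fibre-layer boundary and for the BM — the BM line is taken
   at the posterior margin of the RPE/BM complex;
4. an **active contour** smooths the BM trace: explicit-Euler minimisation of
   tension (α = 0.1) and stiffness (β = 1.0) internal energy plus an image
   term that attracts the contour to the falling-gradient edge map. The step
   (0.5 px initially) is backtracked whenever a trial move would raise the
   energy, so the energy path is non-increasing by construction; refinement
   stops when the largest displacement falls below 0.01 px or after 200
   iterations. Attraction to the *edge* map rather than the band-centre
   ridge keeps the smoothed contour on the same feature the detector
   produced, avoiding a systematic half-band offset.

Columns without a supra-threshold peak are marked invalid rather than
guessed. Manual corrections (a CSV of re-plotted points per scan) overwrite
single columns, and corrected points are hard constraints: the snake treats
them as fixed. Mirror-inversion artifacts near the scan edges are not
auto-detected; the manifest can declare per-scan invalid column ranges, and
the affected map area simply stays uncovered — `coverage` makes the loss
visible. The nerve-fibre-layer boundary is detected for completeness but
feeds nothing downstream.

None of the filter scales or snake weights are dictated by the underlying
method description, which names the filters but not their parameters; all are
exposed in `pipeline_config()` with the defaults above, chosen for band
thicknesses of a few pixels as seen in device exports.

## The color map and coverage

`kappa_to_rgb()` anchors yellow RGB(255,255,0) at κ = 0, green RGB(0,192,32)
at +5×10⁻⁴ 1/µm and red RGB(255,0,0) at −5×10⁻⁴ 1/µm, interpolating linearly
*per channel* toward yellow in between and clamping beyond the saturation
magnitude 1/2000. Channels round half-up, making the mapping bit-exact and
testable. The gradient arithmetic in between the anchors is not specified by
the source description; channel-linear interpolation was chosen and is
configurable through `color_scale()`.

`render_enface()` converts each raster pixel to polar coordinates about the
fovea, looks up κ along the two angularly adjacent half-lines (each of the 12
profiles covers its angle and that angle + 180°), interpolates linearly in
radius and then in angle, and colors the result. Interpolating *curvature*
and then coloring — rather than interpolating RGB — preserves the
zero-crossing ring at a staphyloma edge. A pixel is valid only if both
neighbouring half-lines are valid at its radius, so a fully masked scan
removes its four adjacent sectors (60° of the disk for a 12-line set).
`coverage_of_map()` reports the valid fraction of the 8-mm analysis disk (the
9-mm field minus the two 500-µm stencil margins).

## Eye metrics and the staphyloma rule

All valid κ samples of the 12 profiles are pooled; the package reports the
mean of |κ| and the *population* variance of signed κ. Variance of signed
(not absolute) curvature is the literal reading of "variance of curvature"
and is also the quantity that most cleanly separates smooth bowls from
mosaic, undulated surfaces, where κ alternates in sign. Variance carries
units 1/µm² (source tables print "[1/µm]"; dimensional analysis says
otherwise, and 1/µm² is what the package reports). Pooling on the dense grid
is the default; `metric_sampling = "ascan"` restricts the pool to 500-µm
nodes for sensitivity analyses — the two differ negligibly on smooth
surfaces.

The classifier is a two-threshold AND rule with inclusive boundaries:
staphyloma iff mean |κ| ≥ 7.8×10⁻⁵ 1/µm and var κ ≥ 0.26×10⁻⁸ 1/µm². The
thresholds are the published watershed values; the inclusive reading follows
the "≥" phrasing under which they were reported.

## What the phantoms emulate — and what they do not

`surface_model()` builds the BM surface as a spherical cap (depth relative to
the foveal reference; the wall moves anteriorly off-axis) plus Gaussian
features: a broad positive bowl for a staphyloma and a narrow (σ ≤ 400 µm)
pit for focal choroidal excavation. A Gaussian bowl is the simplest smooth
shape with the right curvature anatomy: a strongly negative floor, an
inflection, and a positive edge ring whenever
`bowl_depth/bowl_sigma² > 1/R`. The defaults (800 µm depth, σ = 1500 µm,
R = 13 mm) satisfy this amply and give a floor curvature of ≈ −4.2×10⁻⁴ 1/µm,
inside the color scale's dynamic range. `render_bscan()` draws a dark
vitreous, bright ILM band, mid-grey retina, bright RPE/BM band and dim
choroid, placing half-intensity transition rows exactly on the ground-truth
boundary rows so that noiseless detection has a well-defined exact answer.
Speckle is multiplicative log-normal (`I·exp(σZ − σ²/2)`), the standard
first-order model of OCT speckle character, applied i.i.d. per pixel and
fully seeded.

The default phantom calibration is 7 µm axial × 15 µm lateral, close to the
roughly 3:1 pixel anisotropy of spectral-domain devices over a 9-mm scan.
This matters: at much stronger anisotropy the steep flanks of a deep bowl
exceed 2 rows per column and no column-wise detector resolves them cleanly.

Phantoms do **not** emulate: fan-beam/optical distortion of scan geometry
(deliberately out of scope — local 1000-µm curvature is insensitive to it),
spatially correlated speckle, vessel shadows, motion artifacts, mirror
inversion, or pathology that disrupts the BM band itself (CNV, atrophy).
Passing phantom tests therefore demonstrates the correctness of the
measurement chain — segmentation, calibration, stencil, map, metrics — not
robustness to every degradation of clinical imagery; on real data the manual
correction and masking paths carry that load, as they did in the original
clinical application, where every eye needed at least some re-plotting.

For classifier validation there is also a *metric-space* generator,
`sample_metric_cohort()`, which draws (mean |κ|, var κ) pairs directly from
correlated log-normal distributions matched to published group means and SDs
(without staphyloma: 5.36 ± 1.24 ×10⁻⁵ 1/µm and 1.35 ± 0.65 ×10⁻⁹ 1/µm²;
with: 13.71 ± 3.50 ×10⁻⁵ and 8.26 ± 6.03 ×10⁻⁹). Log-normal marginals keep
both quantities positive and right-skewed, as variance-type statistics are;
the log-scale correlation (0.85) reflects that both indices grow with ectasia
severity, producing the elongated diagonal cloud real eyes trace out in this
plane. No two-moment fit can reproduce the exact published separation rates
(98.4%/96.2%): any unimodal non-negative law with mean 8.26 and SD 6.03
places several percent of its mass below the 0.26×10⁻⁸ variance cut. The
acceptance check therefore asserts ≥ 90% per-group accuracy as a plausibility
band, and the observed values at the fixed test seed are 92% (with) and 98%
(without).

## Numerical choices and degenerate inputs

* **Ties** in peak search: strict local maxima with ties broken toward the
  vitreous for first-peak searches and toward depth for last-peak searches,
  mirroring the first/last seeding rule.
* **Collinearity**: the stencil returns exactly 0 for exactly collinear
  inputs; interpolated straight lines give |κ| below 10⁻¹⁷ (floating-point
  roundoff only).
* **Short traces**: traces shorter than the 2h stencil span yield an empty
  (all-invalid) profile with a warning, not an error.
* **Gaps**: invalid spans wider than 1000 µm (configurable) are never bridged
  by interpolation; narrower gaps are.
* **Snake divergence**: if no backtracked step can lower the energy, the
  refinement aborts with the iteration count rather than returning a worse
  contour.
* **Degenerate scan sets**: a single-scan set is valid but warned about
  (the en-face renderer needs ≥ 2 distinct angles); duplicate angles are a
  validation error.
* **Empty eyes**: zero valid curvature samples is an error in
  `eye_metrics()`; `write_outputs()` can still serialise the header-only
  artifacts with coverage 0.

## Problem sizes used in the test suite

The shipped tests run phantoms at full protocol fidelity where the property
under test needs it (12 lines, 9-mm field, 1-µm evaluation — about 96,000 κ
samples per eye) and smaller 2–4-line sets where only plumbing is exercised.
The segmentation-recovery and repeatability checks share two seeded
12-line speckle phantoms; the classifier check uses 100 eyes per group.

## Known limitations

Curvature is per-scan-line (1-D section curvature), not surface (2-D)
differential geometry, so oblique features are seen only where scan lines
cross them — matching the radial acquisition protocol. The 9-mm field cannot
contain every staphyloma border. The segmentation assumes a recognisable
bright RPE/BM band; severely degraded images need manual re-plots. The
thresholds are fixed constants taken from a single published cohort and are
exposed as configuration for recalibration on other populations or devices.
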