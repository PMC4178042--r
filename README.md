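# octmap — fundus curvature mapping from radial OCT B-scans

Highly myopic eyes deform at the posterior pole: posterior staphyloma,
chorioretinal atrophy and related complications reshape the back of the eye in
ways that are hard to grade objectively from single cross-sections. `octmap`
quantifies posterior fundus shape from a standard 12-line, 9-mm radial OCT
scan set centred on the fovea. It is aimed at ophthalmic imaging researchers
who need reproducible, per-eye shape indices and en-face curvature topography
from B-scan exports plus a small JSON manifest of scan geometry.

## Method

For each B-scan the Bruch's membrane (BM) line — the shape proxy least
disturbed by retinal pathology — is traced per A-scan with a filter cascade
(median denoising, a Hessian-style layer-structure filter whose first and
*last* supra-threshold depth peaks seed the inner boundaries and the BM, and
signed Sobel depth-gradient refinement), optionally corrected manually, and
smoothed by an active contour (snake). After correcting the anisotropic pixel
calibration so both axes are in micrometres, signed local curvature is
evaluated every 1 µm along the line with a three-point central-difference
stencil of arm h = 500 µm:

    κ(x) = f''(x) / (1 + f'(x)²)^(3/2)
    f'(x)  = (f(x+h) − f(x−h)) / 2h
    f''(x) = (f(x+h) − 2 f(x) + f(x−h)) / h²

with depth f posterior-positive, so κ > 0 where the membrane is convex toward
the vitreous. Each κ maps to a color — yellow RGB(255,255,0) at 0, graded to
green RGB(0,192,32) at +0.0005 1/µm and red RGB(255,0,0) at −0.0005 1/µm,
saturating at magnitude 1/2000 — and the 12 radial profiles are interpolated
angularly into an en-face topography. Per eye, the package reports the mean
absolute curvature, the variance of signed curvature, the valid fraction
("coverage") of the 8-mm analysis disk, and a staphyloma flag that is true
iff mean |κ| ≥ 7.8×10⁻⁵ 1/µm **and** var κ ≥ 0.26×10⁻⁸ 1/µm².

A synthetic module generates layered-retina phantoms over parametric surfaces
(sphere, Gaussian-bowl staphyloma, focal choroidal excavation) with seeded
multiplicative speckle, so the full pipeline is testable without device data.

## Worked example

Analyze a synthetic staphyloma eye end to end:

```r
library(octmap)

ph  <- phantom_eye(surface_model("staphyloma"),      # 800-µm bowl, σ = 1500 µm
                   speckle_sigma = 0.2, seed = 12, eye_id = "staph1")
res <- run_eye(ph$set, out_dir = "staph1_out")
res$metrics
#> <eye_metrics> 'staph1': mean |kappa| = 0.0001207 1/um, var kappa = 2.511e-08 1/um^2,
#>   coverage = 100.0%, n = 96012, staphyloma = TRUE
```

Mean |κ| of 1.21×10⁻⁴ 1/µm (well above the 7.8×10⁻⁵ cut) and curvature
variance of 2.5×10⁻⁸ 1/µm² (above 0.26×10⁻⁸) flag the eye as having a
posterior staphyloma; the generative ground truth for this surface is
1.20×10⁻⁴ and 2.51×10⁻⁸. The written artifacts are a per-point curvature CSV,
a one-row metrics CSV, the en-face map PNG (red floor, green edge ring on a
yellow field) and a JSON run log. A plain sphere phantom
(`surface_model("sphere")`, R = 13 mm) instead yields mean |κ| ≈ 7.7×10⁻⁵ =
1/R with near-zero variance and is classified negative.

The same pipeline runs from the shell:

```sh
exec/octmap analyze --manifest eye01.json --out eye01_results
exec/octmap simulate --spec cohort.json --out cohort_dir
```

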