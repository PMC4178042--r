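Package: octmap
Title: Fundus Curvature Mapping and Staphyloma Quantification from Radial OCT Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies posterior fundus shape in optical coherence tomography
    (OCT). Segments the Bruch's membrane line in 12-line radial B-scan sets with a
    median/Sobel/Hessian filter cascade refined by an active contour, computes
    signed local curvature at 1-micrometre intervals with a three-point
    central-difference stencil of 500-micrometre arms, renders the en-face
    yellow/green/red curvature topography, and summarises each eye by mean
    absolute curvature, variance of curvature and map coverage, with a
    two-threshold posterior-staphyloma classifier. Includes a synthetic phantom
    generator (layered retina over parametric surfaces with multiplicative
    speckle) so the full pipeline is testable without device data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
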