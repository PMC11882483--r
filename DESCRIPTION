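Package: ulmvasc
Title: Ultrasound Localization Microscopy Pipeline for Microvascular
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for super-resolution
    ultrasound localization microscopy (ULM) of microvascular networks.
    Generates synthetic vascular phantoms with microbubble flow under a
    Poiseuille profile and known ground truth, separates bubble signal
    from tissue clutter by singular value decomposition with automatic
    threshold selection, localizes bubbles to sub-pixel precision by
    radial symmetry, links detections into trajectories by optimal
    assignment, accumulates super-resolved density, velocity and
    direction maps, extracts a vessel graph from the reconstruction, and
    computes structural and hemodynamic metrics per region of interest
    (vascular density, diameter, branches, branch points, curvature,
    box-counting fractal dimension, orientation variance, velocity, flow
    volume) together with the normality-gated group-comparison and
    correlation statistics used to contrast tumor core, invasive zone
    and normal tissue.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
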