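Package: spinemorph
Title: Dendritic Spine Morphometry from Light-Microscopy Triangle Meshes
Version: 0.1.0
Authors@R:
    person("Spinemorph", "Developers", email = "spinemorph@example.org",
           role = c("aut", "cre"))
Description: Automated measurement of dendritic-spine morphology from 3D
    triangle meshes reconstructed from light microscopy. Classifies spine
    reconstructions by completeness, repairs missing or fragmented necks by
    cylinder bridging, separates spine heads from necks with shape-diameter
    and skeleton-distance features combined through a Gaussian mixture model
    and graph-cut smoothing, and computes per-spine morphometrics (head
    volume, sphericity, neck length and diameter, spine length and volume).
    Includes population statistics used in spine morphometry studies
    (log-binned density histograms, Mann-Whitney U tests, Spearman
    correlation with Wald slope tests, Hartigan's dip test in 1D and
    projection-based 2D/3D extensions), a passive spine-neck electrical
    resistance model, and a synthetic spine-mesh generator with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
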