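Package: trapacuity
Title: Spatial-Acuity-Based Design and Analysis of Patterned Sticky Traps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing patterned sticky traps around the spatial
    resolution limits of an insect receiver. From an interommatidial angle the
    package computes resolvable pattern sizes and viewing distances, derives
    the three-dimensional visibility geometry of traps hung above a crop
    canopy, classifies multi-trap layouts as choice or no-choice, builds
    photoreceptor spectral-sensitivity curves from a visual pigment template,
    composes and renders flower-patterned trap cards as SVG, and simulates and
    analyses trap-capture experiments with log-link count regression,
    quasi-dispersion correction, and quadratic attraction-range estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
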