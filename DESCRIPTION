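Package: confield
Title: Connective-Field Modeling of Retinotopic Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Explains per-vertex BOLD time courses throughout the brain as
    Gaussian-weighted samples of the primary visual cortex (V1) surface.
    Implements stimulus-referred population receptive field (pRF) fitting,
    heat-method geodesic distances on triangular surface meshes, Gaussian
    connective-field (CF) model fitting with leave-one-run-out
    cross-validation and correction against a nontopographic null model,
    translation of CF fits into visual-field coordinates, and weighted
    statistics for comparing retinotopic connectivity across cognitive
    states. A seeded synthetic-data generator with planted pRF/CF ground
    truth makes every stage testable without external neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    signal,
    stats,
    utils,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
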