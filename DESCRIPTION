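Package: pfalesion
Title: Pulsed-Field-Ablation Lesion Assessment in the Potato Tuber Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bench-testing toolkit for pulsed-field-ablation (PFA) lesion
    assessment in the Solanum tuberosum slice model. Solves the stationary
    conduction problem for a two-needle-electrode geometry over heterogeneous
    conductivity (finite-volume discretization, matrix-free preconditioned
    conjugate gradients), quantifies stained lesions from calibrated top-view
    and cut-view photographs (brightness-threshold segmentation, area, Feret
    length/width, depth), estimates lesion volume by similarity-scaled
    cross-sectional areas integrated with the trapezoidal rule, and calibrates
    the lethal electric-field threshold by matching measured lesion area to
    simulated field superlevel sets. Includes a ground-truthed synthetic image
    generator so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    EBImage,
    pracma,
    stats,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
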