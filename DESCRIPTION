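Package: detem
Title: Energy-Margin Planning and Robustness Evaluation for Distal-Edge-Tracking Proton Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale treatment-planning and robustness-evaluation pipeline
    for intensity-modulated proton therapy delivered with distal edge tracking
    (DET). Builds synthetic voxel phantoms with clinical/planning target
    volumes and a surrounding ring structure, places pencil-beam spots on the
    distal edge of the planning target volume via water-equivalent
    path-length ray tracing, assigns each spot a per-spot energy margin in
    the beam's-eye view, optimizes nonnegative spot weights against
    dose-volume objectives with an iterative least-squares scheme, simulates
    fractionated delivery under random rigid setup shifts, and reports
    dose-volume-histogram variation in normalized total dose.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
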