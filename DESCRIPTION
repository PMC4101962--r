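Package: multiport
Title: Collision-Free Multiport Drill-Trajectory Planning for the Lateral
    Skull Base
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Preoperative planning of straight keyhole drill trajectories
    through the temporal bone. Reads labeled CT volumes (NIfTI), extracts
    watertight triangle surfaces by isosurfacing, computes exact minimum
    distances between candidate drill axes and critical anatomical
    structures, enumerates all collision-free trajectories from a skull
    entry region to a target under drill-radius, safety-distance and
    drill-inaccuracy margins, and selects an optimal set of three ports by
    clearance and cumulative angle, with cylinder merge-length and
    per-region diameter summaries. Includes a synthetic temporal-bone
    phantom generator with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
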