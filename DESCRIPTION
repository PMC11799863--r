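Package: psitunnel
Title: Virtual Planning and Accuracy Evaluation of Femoral Bone Tunnels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for in-silico evaluation of femoral bone-tunnel drilling
    accuracy in multi-ligament knee reconstruction. Builds per-knee
    anatomical coordinate frames, plans tunnel trajectories at prescribed
    axial/coronal angulations from ligament footprints (LCL, popliteal
    tendon, MCL, POL), generates watertight synthetic distal-femur meshes,
    simulates freehand and patient-specific-instrumentation (PSI) execution
    error from quartile-calibrated log-normal models, rigidly overlays
    post-operative onto pre-operative bone with an iterative closest point
    (ICP) algorithm, computes angular-deviation and entry-point accuracy
    metrics, checks tunnel convergence, and compares groups with exact
    Mann-Whitney and Levene tests.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
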