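Package: aptakinetics
Title: Single-Molecule FRET Kinetics and Flow-Cell Biosensor Simulation for
    Aptamer-Protein Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to decode aptamer-protein binding kinetics from
    single-molecule FRET time traces and to translate those kinetics into
    predicted biosensor performance. Includes a ground-truthed simulator of
    two-state binding traces (exponential dwells, frame integration,
    donor-only photophysics), intensity-threshold trace segmentation with
    Gaussian-mixture classification of FRET populations, dwell-time analysis
    with left-truncated exponential maximum likelihood giving k_on, k_off and
    K_d, a finite-volume advection-diffusion solver for a flow cell with
    Langmuir surface binding at the sensor wall, and quartz crystal
    microbalance (QCM) signal processing (Sauerbrey conversion, baseline and
    smoothing, capture slopes, sensitivity, dissociation and regeneration).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    mclust,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
Suggests:
    deSolve,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
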