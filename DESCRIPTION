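Package: stnconn
Title: Structural and Resting-State Functional Connectivity of the Subthalamic Nucleus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the connectivity of the subthalamic nucleus (STN) from
    tractography streamlines and resting-state BOLD fMRI. Implements a
    length-weighted streamline-count structural connectivity measure with
    group-level testing, a monosynaptic ("hyperdirect" pathway) streamline
    filter, per-seed-voxel connectivity mapping across the nucleus, forward
    (whole-brain) and reverse (per-STN-voxel) confound-adjusted seed
    regression of BOLD signals, Fisher z group inference with random-field
    theory cluster-extent thresholding, and a synthetic-data module (toy
    atlases, streamline simulator, BOLD simulator) so that the whole pipeline
    is testable without any imaging downloads. Streamlines are exchanged as
    VTK legacy polydata, volumes as NIfTI-1, and tables as TSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
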