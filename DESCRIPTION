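Package: taskfmriqc
Title: Quality Control for Task fMRI Runs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative and qualitative quality control for task-based
    fMRI datasets in BIDS layout. Reads per-run events tables, motion
    confounds, and preprocessed 4D BOLD images; computes framewise
    displacement and censors high-motion frames (criterion A); screens
    task presentation (criterion B) and behavioral attentiveness
    (criterion C); computes voxelwise temporal mean, standard deviation
    and tSNR maps with review montages and acquisition-metadata
    consistency checks (criterion D); and assembles per-run and
    dataset-level HTML reports plus a machine-readable decision record.
    A synthetic-data module generates events, motion traces and 4D
    ellipsoid phantoms with known ground truth so every stage is
    testable without real data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    png,
    withr,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
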