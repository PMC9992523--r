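Package: habmpm
Title: Synthetic Multi-Parameter Mapping and Habenula Microstructure Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for quantitative MRI
    multi-parameter mapping (MPM) of the habenula. Generates digital
    habenula phantoms, forward-simulates multi-echo spoiled FLASH
    acquisitions with T1/PD/MT weighting, estimates R1, R2*, PD and MTsat
    maps (joint ESTATICS R2* fitting, dual-flip-angle rational
    approximation, transmit-bias-corrected MT saturation), and runs
    native-space ROI statistics, volumetry and contrast-to-noise analysis
    as well as group-space probability-atlas and threshold-sweep analyses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
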