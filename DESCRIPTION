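Package: lumicon
Title: Contrast and Luminance Encoding in Fly Visual Interneurons and Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stimulus generation and quantification pipeline for studying how
    first-order visual interneurons (the lamina monopolar cells L1, L2 and L3 of
    Drosophila) and optomotor behavior encode contrast and luminance. Builds
    photometrically calibrated LED-arena stimulus protocols (moving ON/OFF edges,
    luminance staircases, randomized full-field flashes, adapted A/B contrast
    steps), simulates model-neuron calcium recordings and model-fly trackball
    sessions with ground truth, and implements the analysis chain: image-stack
    registration, ROI trace extraction, dF/F, trial averaging, polarity
    filtering, step/plateau/peak/sustained/edge response metrics, sigmoidal
    contrast-response fits with bootstrap, mutual information and non-linearity
    indices for luminance encoding, yaw-velocity trackball processing,
    log-luminance slope fits, rescue-efficiency permutation tests, and the
    hierarchical (ROIs-within-flies) statistical conventions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    nortest,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
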