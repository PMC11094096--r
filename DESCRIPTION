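Package: slicephys
Title: Hippocampal Slice Electrophysiology, Synapse Imaging and Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-cell patch-clamp recordings and
    fluorescence imaging of hippocampal circuits: passive membrane and
    excitability measures, template-matched detection of spontaneous and
    miniature synaptic currents, AMPA/NMDA charge decomposition and tonic
    NMDA-current estimation, synaptic puncta colocalization and glial
    morphology quantification, Sholl and spine morphometrics, liquid
    junction potentials by the Henderson equation, and the accompanying
    statistical procedures. Ships a synthetic-data generator with recorded
    ground truth so every stage is testable without experimental data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    minpack.lm,
    nortest,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
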