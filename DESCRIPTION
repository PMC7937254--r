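Package: dibhmargin
Title: Variance-Component PTV Margins from Cine Portal Imaging During
    Breath-Hold Breast Radiotherapy
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify chest-wall positional errors during deep
    inspiration breath-hold (DIBH) breast radiotherapy from cine portal
    (EPID) image streams and to translate them into planning target volume
    (PTV) margins. Includes a Canny-style chest-wall edge tracker with
    sub-pixel localization, restricted maximum likelihood (REML) estimation
    of inter-patient, inter-fraction and intra-fraction variance components
    under a nested random-effect model, the van Herk margin recipe with
    fraction-number-dependent effective errors, and a synthetic-data module
    (error traces, abdominal respiration traces, and portal-image-like frame
    stacks) so the whole pipeline is testable without clinical data.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
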