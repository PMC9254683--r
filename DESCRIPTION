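Package: lagcvr
Title: Lagged-GLM Cerebrovascular Reactivity Mapping and Its Coupling with
    Baseline Perfusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates BOLD cerebrovascular reactivity (CVR) from end-tidal
    CO2 recordings using voxelwise multiple regression with hemodynamic lag
    optimization, quantifies baseline cerebral blood flow from
    pseudo-continuous arterial spin labeling with the single-compartment
    consensus model, computes resting-state fluctuation amplitude metrics
    (ALFF, fALFF, mRSFA), and relates CVR to baseline perfusion through
    gray-matter summary correlations with influence screening, parcelwise
    rank correlations with Fisher Z inference, and permutation
    repeated-measures ANOVA. Includes a fully seeded synthetic multi-subject
    study generator with known ground truth, so every stage of the pipeline
    can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
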