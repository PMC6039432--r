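Package: fretscreen
Title: TR-FRET High-Throughput Screening Triage and Quantitative Binding Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for TR-FRET (HTRF) protein-protein interaction
    screening campaigns in 384-well format: per-well FRET-ratio normalization,
    plate quality control by the Z'-factor, percent-inhibition hit calling, a
    monomolecular counter-screen to deconvolve assay interferers from genuine
    interaction inhibitors, dose-dependence triage with four-parameter
    log-logistic IC50 fitting, and dissociation-constant estimation from
    fluorescence-polarization titrations with the exact (ligand-depletion)
    quadratic binding isotherm. Includes seeded generators for synthetic
    screening campaigns, dose series and polarization titrations with truth
    tables for pipeline evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
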