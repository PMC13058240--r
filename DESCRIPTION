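Package: dyecomp
Title: Pairwise Bacterial Competition Assays with Transient Fluorescent Staining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying pairwise competition between bacterial
    genotypes or species when one competitor is transiently stained with a
    fluorescent dye and cocultures are measured by imaging flow cytometry.
    Provides two-stage gating of single-cell event tables (polygon gate on
    dye and autofluorescence intensity plus a brightfield-area range),
    ROC-based derivation of stained/unstained classification thresholds from
    monoculture controls, coculture frequency estimation with Wilson
    confidence intervals and optional misclassification correction,
    reconciliation against dilution-plating colony counts (30-300 colony
    rule), frequency-trajectory and carrying-capacity statistics, and a
    ground-truth-labelled synthetic-data simulator in which the dye signal
    halves with each cell division.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
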