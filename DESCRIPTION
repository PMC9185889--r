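Package: persignal
Title: Perturbation-Response Modeling of Kinase Inhibitor Resistance Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational analyses behind kinase-inhibitor
    resistance studies in cancer cell lines: gene-level enrichment scoring of
    pooled CRISPR knockout screens from sgRNA count tables, four-parameter
    logistic dose-response fitting with absolute IC50/GI50 and collateral
    sensitivity matrices, and a steady-state modular-response model of
    receptor-MAPK-PI3K signaling fitted to MIDAS-formatted perturbation data.
    Model parameters can be linked across isogenic cell lines and released
    one at a time by likelihood-ratio testing, which localizes rewired
    interactions such as a weakened ERK-to-RAF negative feedback. Includes
    ground-truth synthetic data generators for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    DESeq2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
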