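Package: nanoRF
Title: In-Silico Fractionation of Protein Complexes from Multi-Knockout
    SILAC Chromosome Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Targeted Random-Forest ("nanoRF") analysis of quantitative
    SILAC proteomics data from panels of conditional knockouts. Converts
    replicate-level knockout/wild-type SILAC ratios into per-condition
    dependence profiles, scores every detected protein's co-fractionation
    with a target complex using a Random Forest trained on a very small
    positive set (out-of-bag adjusted scores), quantifies fractionation
    quality by ROC/AUC and the Matthews correlation coefficient, clusters
    multi-complex score profiles into branches to nominate novel
    complex-associated candidates, and simulates knockout-perturbation
    SILAC datasets with planted complexes for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    randomForest,
    stats,
    utils,
    yaml,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
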