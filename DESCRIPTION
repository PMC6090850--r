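Package: neutrokit
Title: Analytics for Neutrophil-Like Cell Line Differentiation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable analysis toolkit for experiments that differentiate
    HL-60/PLB-985 myeloid cell lines into neutrophil-like cells and compare
    them with primary neutrophils. Implements uniform-gene FPKM
    normalization with log10 flooring and equal-lab-weight replicate
    averaging, cross-sample Spearman similarity with average-linkage
    clustering and floored PCA, control-derived flow-cytometry gating
    statistics (percent positive, normalized MFI, autofluorescence
    correction, death fraction), chemotaxis trajectory directionality
    (angular bias, speed, direction histograms) with a mixed-population
    simulation, SNP genotype concordance for cell-line identity, nuclear
    morphometry from two-channel fluorescence images, and a searchable
    merged expression catalog. Seeded synthetic-data generators emulate
    every input so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    ape,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
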