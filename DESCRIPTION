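Package: senescreen
Title: Consensus Senescence Markers and Senescent-Cell Detection in Bulk and
    Single-Cell Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives consensus cellular-senescence marker panels from multiple
    bulk transcriptome datasets using empirical-Bayes moderated differential
    expression, calls senescent cells in single-cell expression matrices with a
    four-criterion classifier (cumulative up-marker expression, absence of
    down-markers, high SASP and ECM expression, CDK-inhibitor positivity),
    detects senescence-escape cells, scores anatomic regions for
    senescence-marker enrichment, tests ligand-receptor communication between
    cell clusters by permutation, and quantifies mRNA-protein concordance and
    proteome/marker-panel overlap. Ships seeded synthetic-data generators that
    emulate every input with planted ground truth so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    generics,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
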