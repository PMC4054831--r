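Package: salivamix
Title: Cell-Type Composition Adjustment and Paired EWAS for Saliva Methylomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for epigenome-wide association studies on DNA methylation
    array data from heterogeneous body fluids such as saliva. Implements a
    marker-CpG-based strategy for adjusting beta values for variable
    cell-type composition (screening discriminative CpGs against a
    two-cell-type reference panel, mixture proportion estimation, selective
    linear-regression adjustment), paired exact Wilcoxon signed-rank testing
    with methylation-variable-position calling, the Freeman-Halton exact
    test for r x c contingency tables, power analysis for paired designs,
    read-level bisulfite amplicon validation statistics, and primer-extension
    (SNuPE/SIRPH) methylation indices. A seeded synthetic-data generator
    emulating two-cell-type mixtures in a twin-pair design makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
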