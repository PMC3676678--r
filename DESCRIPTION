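Package: museomics
Title: Mitogenome Capture Pipelines and Macroevolutionary Tests for Museum Specimens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing mitochondrial genomes from degraded,
    barcoded, target-captured sequencing libraries of museum specimens, and
    for the downstream macroevolutionary analyses such data feed. Includes a
    ground-truth synthetic read/tree/range generator, minimum-Hamming-distance
    barcode design and exact-match demultiplexing, quality filtering and
    overlap merging of mate pairs with consensus qualities, iterative
    reference-guided consensus assembly on circular references with duplicate
    collapsing and 2-fold-coverage calling, competitive-alignment
    contamination classification with exact binomial confidence intervals and
    closed-form numt error models, birth-death-likelihood diversification
    model selection with parametric-bootstrap rate-shift tests, gridded
    range-overlap regression tests of allopatric speciation, and a
    Felsenstein-pruning likelihood engine with the Shimodaira-Hasegawa test
    via RELL resampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    S4Vectors,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
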