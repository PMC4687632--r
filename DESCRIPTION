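Package: ReceptorScreen
Title: Immunoreceptor Candidate Discovery from Sequence and Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable implementation of an immunoreceptor discovery
    screen for mast cells. Starting from protein sequences, CDD-style
    domain annotations and paired human/mouse expression matrices, the
    package segments each protein into extracellular, transmembrane and
    cytoplasmic regions, classifies extracellular Ig-like and C-type
    lectin-like domains, scans cytoplasmic tails for ITAM, ITIM, ITIM-like
    and PI3K-binding signaling motifs and catalytic kinase/phosphatase
    domains, applies expressed-gene and abundance filters with
    max-over-samples cell-type aggregation, scores cross-cell-type
    expression specificity as the average fold change against comparison
    cell types in both species, and ranks the surviving candidate genes.
    A seeded synthetic-fixture generator with planted ground truth makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    Biostrings,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'annotation.R'
    'expression.R'
    'motifs.R'
    'proteins.R'
    'screen.R'
    'synthetic.R'
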