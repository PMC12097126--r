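Package: apadyn
Title: Alternative Polyadenylation Dynamics Across Tissues and Developmental Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies 3'-UTR alternative polyadenylation (APA) from
    isoform-level polyA-site (pAS) expression tables: polyA-site usage (PAU)
    and proximal usage (PPAU), positional pAS classification
    (SPA/proximal/middle/distal), weighted 3'-UTR length, APA complexity
    (PAU entropy) and tissue specificity, developmental PPAU trajectory
    clustering with trend scoring, sequence-determinant profiling
    (polyA-signal hexamers, +1 nucleotide, positional composition,
    conservation with coding masking), and regulatory-context analyses
    (RBP motif enrichment in alternative vs constitutive UTRs, CLIP-peak
    overlap, miRNA-site density, transposable-element coverage). Includes a
    fully deterministic synthetic-data generator with a ground-truth
    manifest for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    cluster,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
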