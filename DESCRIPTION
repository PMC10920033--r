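Package: conaccr
Title: Detection of Conserved Elements and Lineage-Specific Accelerated
    Regions from Multi-Species Genome Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Phylogenetic scan pipeline for detecting evolutionarily
    conserved elements (all-branch CEs) and lineage-specific accelerated
    regions (ARs) from reference-anchored multiple genome alignments.
    Curates pairwise alignments (ambiguous-base trimming, overlap
    resolution, species-count filtering), fits a neutral GTR(+gamma)
    substitution model on unbiased fourfold-degenerate sites selected by
    relative synonymous codon usage, segments alignments by annotation
    category with priority rules, runs per-window likelihood-ratio tests
    for conservation and branch acceleration with CONACC scores and
    Benjamini-Hochberg FDR element calling, and performs downstream gene
    association, ncRNA-overlap filtering, and enrichment analyses. A
    synthetic-data module generates eight-taxon alignments with implanted
    conserved and accelerated regions for calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
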