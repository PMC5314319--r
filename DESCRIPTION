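Package: uvomics
Title: Integrative Analysis of UV-Induced Epigenomic, Transcriptomic and
    Genetic Dysregulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the molecular response of skin cells to
    ultraviolet irradiation by integrating H3K27ac ChIP-seq, RNA-seq and
    exome sequencing readouts. Implements gene-level differential H3K27
    acetylation calling from peak signal, rank-ordering super-enhancer
    identification with a scaled-curve transition-point cutoff, integration
    statistics linking acetylation and expression fold changes,
    Kolmogorov-Smirnov gene-set enrichment with gene-shuffling permutation
    p-values, hypergeometric pathway enrichment, single-nucleotide variant
    genomic-feature and substitution-spectrum profiling, and an
    Achilles-style shRNA depletion-score pipeline for lineage-specific gene
    essentiality. Seeded synthetic-data generators with planted ground
    truth make every stage testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
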