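Package: texapt
Title: Transposable-Element Exaptation Analysis for ChIP-seq Peak Sets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for studying how transposable elements (TEs)
    overlapping transcription-factor ChIP-seq peaks host combinatorial
    binding-site arrangements.  Implements TE-family enrichment z-scores
    against locally matched Monte Carlo peak resampling, position weight
    matrix scanning with per-matrix score thresholds calibrated to a fixed
    random-sequence hit rate, the Transposon Affinity Score (the fraction of
    a family's peak-overlapping instances carrying a factor's motif),
    fixed-distance motif-pair spacing correlators with a permutation null,
    TSS-window peak-to-gene association with hypergeometric category
    enrichment, and syntenic projection of TE annotations between two
    genomes to identify conserved instances.  A synthetic-data module
    generates genomes, decayed TE families with planted motifs, peak sets
    with controlled enrichment, genes, and a syntenic second genome with
    full ground truth, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
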