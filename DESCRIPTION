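Package: famsurvey
Title: Gene Family Census, Duplication Dating and Nodule Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide surveys of plant gene
    families, modelled on papain-like cysteine protease (PLCP) surveys in
    legumes. Identifies family members from protein sequences and conserved
    domain annotations with rule-based pseudogene calling, detects tandem
    duplication clusters and whole-genome-duplication (WGD) segment pairs
    with collinearity and phylogeny validation, estimates Ka/Ks by the
    Nei-Gojobori (1986) method and dates duplications from synonymous
    divergence, builds neighbor-joining trees with bootstrap support and
    clade group assignment, summarises exon/intron/UTR gene structures, and
    analyses root-nodule-symbiosis expression time courses (geNorm reference
    stability, efficiency-corrected relative quantification, temporal
    pattern classification). Ships a synthetic-genome simulator with known
    duplication history, pseudogenes and expression classes so that every
    stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    ape
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
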