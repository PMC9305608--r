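Package: DomestiScan
Title: Selective-Sweep Scanning, Haplotype Tracking and Candidate-Gene
    Prioritisation Across a Crop Domestication Series
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the loss of nucleotide diversity and the
    turnover of gene haplotypes that accompany crop domestication and
    improvement, modelled on the wheat (Triticum) wild-to-cultivar series.
    Provides windowed nucleotide diversity (pi) and Weir-Cockerham Fst from
    phased multi-sample genotypes, pi-ratio/Fst top-quantile selective-sweep
    calling, per-gene diplotype haplotype catalogues with major-haplotype
    tracking across an ordered lineage series, QTL co-location, the tau
    tissue-specificity index with expression clustering and family
    enrichment, Nei-Gojobori dN/dS with divergence-time conversion, and a
    multi-evidence candidate-gene report. A built-in Wright-Fisher
    bottleneck simulator generates complete synthetic fixtures (VCF, GFF3,
    panel, QTL, expression tables) with implanted sweeps for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
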