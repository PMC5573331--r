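Package: srnaphase
Title: Plant Small RNA Locus Discovery, Phasing Statistics and Degradome Target Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A transcript-based analysis toolkit for plant small RNA sequencing
    studies. Discovers conserved and novel miRNA loci from fold-back precursor
    structure (homology search, hairpin and MIRcheck-style duplex filters,
    miRNA-star evidence), detects phased siRNA (phasiRNA) loci with a
    hypergeometric register P-value and a phase score over sliding 210-nt
    windows with the 2-nt antisense offset, identifies TAS3 loci from dual
    miR390 complementary sites flanking conserved tasiARF sequences, validates
    miRNA and tasiRNA targets with degradome (PARE) 5-prime end profiles and
    SeqTar-style mismatch rules, and tests count-based differential abundance
    between biomass groups defined from phenotype tables. A synthetic-data
    generator produces transcriptomes with planted hairpins, phased registers,
    degradome peaks, negative-binomial count libraries and correlated
    phenotype tables so every stage is testable without sequencing archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    MASS,
    Rcpp,
    methods,
    rtracklayer,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
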