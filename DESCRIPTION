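Package: SLscout
Title: Spliced Leader Gene Discovery from Stranded RNA-Seq
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies dinoflagellate spliced-leader (SL) genes from stranded
    RNA-seq libraries. Sense-strand (R2) reads are screened for the 21-nt
    dinoflagellate SL, its 17-nt relict, and a TCG-variant first unit;
    SL-bearing reads are assembled into locus consensus sequences by greedy
    ungapped overlap clustering with majority-vote consensus; loci are
    classified as single-SL, tandem-SL, or SL-like genes; candidate introns
    downstream of the SL are checked for GT/GC donor dinucleotides and scanned
    for U-rich Sm-protein binding motifs against a uniform-background
    expectation. A ground-truthed simulator generates stranded paired-end
    libraries with planted SL loci so every stage of the pipeline can be
    verified end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
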