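Package: cephamir
Title: miRNA Target-Site Conservation, RNA Editing, and Transcriptome
    Architecture Analyses for Cephalopod Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the post-transcriptional regulatory
    landscape of cephalopod (octopus) transcriptomes. Derives miRNA
    response elements (8mer seed-match sites with a trailing adenosine)
    from mature miRNA sequences, scans orthologous 3'UTR pairs and scores
    positional site conservation conditioned on miRNA-mRNA codetection,
    with dinucleotide-preserving shuffled controls and Mann-Whitney group
    tests. Calls A-to-I editing sites from pileups, computes per-feature
    editing indices and miRNA seed-editing levels, and intersects editing
    with target sites. Computes mappability-adjusted exon-skipping and
    intron-retention rates with a cross-tissue subsampling protocol, and
    clusters long-read 3'-end tags into cleavage sites with
    polyadenylation-signal assignment. A synthetic-data generator with
    known planted parameters makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
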