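Package: wrkymine
Title: Genome-Wide Mining and Characterization of WRKY Transcription Factors
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated toolkit for genome-wide identification and
    characterization of WRKY transcription-factor gene families in plant
    genomes. Detects WRKY domains (conserved heptapeptide plus C2H2/C2HC
    zinc finger), collapses redundant annotation to unique genomic loci,
    classifies family members into groups I/II/III and subgroups IIa-IIe,
    builds neighbor-joining phylogenies with bootstrap support from a
    native progressive aligner, discovers ungapped motifs by ZOOPS
    expectation-maximization, scans 3000-bp promoters for cis-regulatory
    elements including the bipartite double W-box, computes theoretical
    protein molecular weight and isoelectric point, and quantifies
    relative expression from qPCR Ct tables by the comparative 2^-ddCt
    method with ANOVA and Tukey letters. Ships deterministic synthetic-data
    generators with ground-truth manifests so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    multcomp
Config/testthat/edition: 3
biocViews: Genetics, SequenceMatching, Phylogenetics, MotifDiscovery,
    GeneRegulation, Transcription
RoxygenNote: 7.3.3
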