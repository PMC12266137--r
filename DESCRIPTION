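Package: spliceaso
Title: Design and Evaluation of Splice-Modulating Antisense Oligonucleotides
    for Deep-Intronic Pseudoexon Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for characterizing deep-intronic delins variants that
    activate ectopic splice sites and for designing steric-block antisense
    oligonucleotides (ASOs) against the resulting pseudoexons. Implements
    per-haplotype consensus reconstruction from phased read pileups,
    pseudoexon percent-spliced-in (PSI) quantification from junction reads
    with Wilson confidence intervals, long-read isoform assignment by exact
    junction-chain matching, open-reading-frame scanning with premature
    termination codon and nonsense-mediated decay annotation, 1-nt tiled
    18-mer ASO candidate generation with GC/homopolymer/off-target filters,
    a provably complete seed-indexed hybridization off-target search,
    qPCR 2^-ddCt quantification, screen hit calling, and absolute EC50/IC50
    estimation by four-parameter logistic fits. A synthetic-locus module
    emulates a two-haplotype gene carrying a 9-to-19 nt intronic delins so
    every stage is testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
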