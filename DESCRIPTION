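Package: enrichQC
Title: Quality Control for Hybridization-Capture Enrichment of Ancient DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation framework for in-solution hybridization-capture
    (target-enrichment) experiments on degraded and ancient DNA. Builds SNP-panel
    target geometries and the comparable/noncomparable partition between two
    probe designs, classifies aligned reads and computes on-target rate, target
    efficiency, fold enrichment, expected coverage and SNP coverage evenness,
    summarises GC-bias dropout, profiles cytosine deamination (C-to-T) at read
    ends, counts alleles at panel SNPs with a threshold genotyper and genotype
    concordance rule, and tests for allelic capture bias with a quasibinomial
    model. A synthetic ancient-DNA capture simulator with per-read truth tables
    makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
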