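Package: uvsig
Title: UV Mutational Signature Enrichment and Neoantigen Hydrophobicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies ultraviolet (UV) mutagenesis in tumor variant sets and
    its biochemical consequences. Implements a trinucleotide-context enrichment
    score (UVMSE) that measures how strongly a sample's single-nucleotide
    substitutions are enriched for a strand-resolved UV mutational signature,
    an iterative probabilistic in-silico UV mutagenesis simulator over all
    hexanucleotide (two-codon) stretches that tracks exome-wide Kyte-Doolittle
    hydrophobicity drift, amino-acid composition and stop-codon gain, a
    neopeptide (8-10-mer) hydrophobicity analysis relating per-sample
    hydrophobicity change to UV-weighted mutation load, and cohort
    stratification utilities (ROC thresholding, Fisher odds ratios,
    Kaplan-Meier / log-rank) for relating UV signature enrichment to
    immunotherapy outcome. Seeded synthetic-data generators (reference
    sequence, signature-mixed variant sets, toy transcriptomes and outcome
    cohorts) make every analysis testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Matrix,
    methods,
    pROC,
    Rsamtools,
    rtracklayer,
    stats,
    survival,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
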