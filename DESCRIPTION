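Package: scwga
Title: Evaluation Framework for Single-Cell Whole-Genome Amplification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for single-cell whole-genome
    amplification (WGA) experiments. Provides a branching-process simulator of
    exponential (MDA-like) versus quasilinear (terminator-limited, PTA-like)
    amplification; coverage-uniformity statistics (CV, MAPD, Lorenz curve,
    Gini index, breadth); bulk-referenced SNV sensitivity, discordance,
    allelic-dropout and mutation-spectrum metrics with non-negative
    least-squares signature reconstruction; kindred-cell variant
    classification with sensitivity-corrected per-cell somatic mutation rate
    estimation; mutagen-exposure analysis (per-cell mutation counting, dose
    response, DNase-hypersensitive-site enrichment); and CRISPR off-target
    site enumeration with indel and structural-variant attribution.
    Synthetic data generators with recorded ground truth supply all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
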