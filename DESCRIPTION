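Package: biasbench
Title: Measuring, Categorizing and Scanning for Reference Bias in Short-Read Alignments
Version: 0.1.0
Authors@R:
    person("Bias", "Bench", email = "maintainer@biasbench.dev", role = c("aut", "cre"))
Description: Tools to measure reference bias in short-read alignments of diploid
    genomes. Implements three allelic-balance measures at heterozygous sites
    (simulation, mapping and assignment balance), naive and context-aware
    read-to-haplotype assignment with variant cohorts and effective-variant
    extension in repeats, a geometric classifier of bias events
    (loss/flux/local/outlier), a two-feature per-site bias predictor with
    ROC/PR evaluation, and a reference-free windowed scan that calls biased
    regions from pileups and compares alignment workflows. Ships a synthetic
    fixture generator (reference, phased VCF, diploid consensus, truth-tagged
    simulated reads, idealized aligner and bias-injection utilities) so the
    whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    IRanges,
    Biostrings,
    jsonlite,
    ggplot2,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
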