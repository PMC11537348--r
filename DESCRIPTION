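Package: hostguard
Title: Host Read Filtration and Re-Identification Auditing for Metagenomics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computational removal of host (human) DNA reads from metagenomic
    sequencing data and auditing of the privacy consequences of incomplete
    filtration. Computes exact per-position matching statistics of reads
    against reference collections, transforms them into per-read host scores
    (maximum, average, and a run-aware custom metric) with thresholds derived
    from a theoretical host read, and composes length, alignment-surrogate,
    and index-based filtration stages into three pipeline topologies for
    single- or paired-end FASTQ. Includes a labeled read simulator with
    missing-reference-region and shared low-complexity-segment failure modes,
    a benchmarking layer (ground-truth evaluation, exact Wilcoxon signed-rank
    comparisons, threshold grid search, coverage depth/breadth diagnostics),
    and a genotype-likelihood re-identification model (per-site likelihoods,
    likelihood scores, Hardy-Weinberg population moments, standardized
    P-values, greedy LD pruning, Bonferroni match calling) with a synthetic
    cohort generator for demonstrating that thorough host filtration destroys
    re-identifiability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    S4Vectors,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
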