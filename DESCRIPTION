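Package: protectscan
Title: Protective-Variant Prioritization and Age-at-Onset Modifier Analysis
    for Exome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a rare-variant prioritization funnel for discovering
    candidate protective alleles in exome-sequenced cohorts stratified into
    resilient carriers, affected carriers, idiopathic cases and controls:
    consequence and deleteriousness (CADD PHRED) filtering, qualifying
    homozygous and compound-heterozygous configurations, stratum exclusivity
    and candidate-gene intersection, with per-stage audit reports. Also
    provides genotype-coded (additive, dominant, recessive) linear-model
    association of a variant with age at disease onset, genotype-frequency
    comparisons against reference populations using gnomAD-style allele
    counts, and a synthetic exome-cohort generator under Hardy-Weinberg
    genotype sampling for end-to-end validation, parameter recovery and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: VariantAnnotation, GeneticVariability, SNP, Genetics,
    StatisticalMethod
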