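Package: strainase
Title: Strain-Specific Genomes, Allele-Specific Expression and Bench
    Statistics for Inbred Mouse Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for diet-by-genotype studies in inbred mouse crosses
    (for example LG/J x SM/J). Builds strain-specific genomes by
    substituting per-strain alleles into a reference, produces indel-aware
    coordinate maps for lifting annotations between reference and strain
    coordinates, assigns F1-hybrid RNA-seq reads to parental haplotypes at
    diagnostic variant sites, and tests per-gene allelic bias with an
    exact binomial test. Includes a permutation test for enrichment of
    candidate genes within QTL intervals using length-matched random
    non-QTL regions, the delta-delta-Ct method for relative qPCR
    quantification, glucose-tolerance-test area under the curve, a Grubbs
    outlier screen, and a normality-gated log10 transform policy. A
    synthetic-data module generates every input with known ground truth
    so the whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
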