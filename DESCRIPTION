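Package: ocaphase
Title: Pedigree-Based Phasing and Classification of the TYR S192Y/R402Q
    Haplotype in Oculocutaneous Albinism
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Resolves the cis/trans configuration of TYR variant pairs
    across pedigrees from unphased genotypes by Mendelian constraint
    propagation, classifies diplotypes into oculocutaneous albinism
    phenotype predictions under a deterministic penetrance model for the
    hypomorphic S192Y/R402Q in-cis haplotype, and computes cohort-level
    enrichment statistics (2x2 chi-squared tests and combined proportions)
    for the haplotype across albinism cohorts with missing heritability.
    Includes a gene-dropping pedigree simulator with configurable founder
    haplotype frequencies so every stage can be validated against known
    truth phase.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
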