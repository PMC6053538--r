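Package: standkin
Title: Target-Capture Design, Genomic Relatedness and Inbreeding in Mixed Tree Stands
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for marker development and
    relatedness estimation in a mixed stand of two hybridizing tree species.
    Provides a synthetic-stand generator (Balding-Nichols species divergence,
    pedigree gene dropping, overdispersed read counts, fitness traits with a
    tunable inbreeding effect, and a toy annotated genome), capture-target
    selection and probe tiling with GC and repeat filters, enrichment and
    reproducibility metrics, a read-count genotype caller with the full
    filtering cascade (depth, intra-individual allele fraction, missingness,
    call rate, Hardy-Weinberg exact test with FDR, LD pruning, minor-allele
    frequency tiers), the VanRaden-form genomic relationship matrix with
    genomic inbreeding as Gii - 1, the pedigree additive relationship matrix,
    per-locus Weir-Cockerham Fst, a two-cluster admixture EM with q-threshold
    species assignment, and Poisson/Gaussian inbreeding-depression
    regressions, orchestrated by a configuration-driven pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    vcfR,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    knitr,
    rmarkdown
Config/testthat/edition: 3
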