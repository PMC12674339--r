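Package: wssgwas
Title: Weighted Single-Step GWAS for Pedigreed, Partially Genotyped Populations
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Single-step GBLUP and weighted single-step genome-wide association
    analysis (WssGWAS) for populations in which only a subset of pedigreed,
    phenotyped animals is genotyped. Provides pedigree algebra (inbreeding,
    sparse A-inverse, genotyped-animal submatrices), genotype quality control,
    VanRaden genomic relationship matrices with SNP weighting, H-inverse
    assembly, AI-REML variance-component estimation, mixed-model-equation
    solving for genomic breeding values, back-solving of SNP effects with
    iterative re-weighting, and 30-SNP sliding-window variance partitioning
    that flags candidate genomic regions. A gene-dropping simulator generates
    pedigrees, genotypes, QTL architectures and phenotypes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
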