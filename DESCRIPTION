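Package: intpath
Title: Integrative Pathway Analysis of GWAS and Gene Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Cross-platform pathway analysis for case/control studies.
    Implements four permutation-based gene-set tests for genome-wide
    association data (a weighted Kolmogorov-Smirnov enrichment score with
    phenotype swapping, SNP-resampling over-representation in the ALIGATOR
    style, the SNP ratio test, and an LD-pruned set-based mean-chi-square
    test), gene set enrichment analysis of two-class expression data ranked
    by signal-to-noise ratio, and Fisher's combined probability test to
    integrate the two platforms. Includes readers for PLINK text
    genotypes, BED gene models, GMT gene sets and expression matrices,
    allelic association with quality control and genomic-inflation
    estimation, SNP-to-gene mapping with a flanking window, derived
    cross-platform gene sets, and a synthetic-data generator with planted
    pathway effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
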