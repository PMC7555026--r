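Package: gxescan
Title: Gene-Based Gene-Environment Interaction Testing via Penalized
    Latent Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene-level tests of gene-environment interaction for
    quantitative traits. All SNPs of a gene are collapsed into a single
    latent component by ridge-penalized alternating least squares, and the
    latent gene-by-environment interaction coefficient is tested by
    phenotype permutation. Includes genotype input (VCF, PLINK binary,
    dosage tables), quality-control filters, SNP-to-gene mapping with
    flanking windows, four p-value-combination competitor tests (minP,
    GATES, truncated tail strength, truncated product), an LD-structured
    synthetic genotype/phenotype generator, and Monte-Carlo harnesses for
    type-I-error and power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
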