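Package: privgwas
Title: Privacy-Preserving Multi-Site GWAS via Randomized Encoding and
    Stacked Ridge Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Server-assisted, multi-party genome-wide association analysis of
    quantitative traits without sharing individual-level data. Implements
    REGENIE-style stacked ridge regression (per-block Level-0 ridge combined by
    a Level-1 ridge fit) both as a centralized plaintext engine and as a
    distributed protocol in which horizontally partitioned cohorts exchange
    only randomized-encoded payloads with an untrusted coordinating server:
    additive-masked count aggregation for quality control, two-sided
    orthonormal obfuscation for covariate projection, consensus ADMM for
    Level-0 ridge, server-side conjugate gradients for Level-1, and a
    distributed single-SNP chi-squared association test. Includes a synthetic
    genotype/phenotype simulator with population structure and family
    relatedness, QC filters (missingness, minor allele frequency,
    Hardy-Weinberg equilibrium), an in-process and a TCP transport with a
    server-transcript audit, blockwise genotype archives, PLINK .bed input,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    digest,
    withr,
    optparse
Suggests:
    testthat (>= 3.0.0),
    callr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
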