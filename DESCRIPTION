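Package: gsindex
Title: Multi-Trait Genomic Selection with Smith Optimum Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-trait genomic prediction and optimum index selection for
    plant breeding panels. Provides SNP quality control and genomic
    relationship matrices from VCF genotypes, Federer adjusted means for
    augmented randomized complete block trials with across-environment
    combination, a Bayesian multi-trait GBLUP model fitted by Gibbs sampling
    with inverse-Wishart priors and missing-phenotype data augmentation,
    Smith optimum selection indices with their heritability, genetic
    correlation and accuracy statistics, repeated hold-out cross-validation
    and named train-to-test trial scenarios (including prediction of ratoon
    regrowth performance from seed-grown trials), and a synthetic-data
    generator that emulates a structured biomass sorghum diversity panel
    with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
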