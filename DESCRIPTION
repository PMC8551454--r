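Package: pleiopath
Title: Causal Pathway Discovery for Pleiotropic Variants in Imaging Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distinguishes horizontal from vertical pleiotropy for genetic
    variants associated with both a continuous brain-imaging mediator
    (white-matter fractional anisotropy) and a smoking phenotype (binary
    smoking status or cigarettes per day). Implements a three-step hybrid
    causal discovery procedure: composite-null false-discovery-rate screening
    for pleiotropic variants, a conditional-independence test separating
    horizontal from vertical pleiotropy, and BIC-based selection between the
    two competing mediation models, followed by effect decomposition,
    indirect-effect inference (Sobel and bootstrap) and mediation-type
    classification. Includes genotype quality control (minor-allele
    frequency, Hardy-Weinberg equilibrium, missingness), smoking-phenotype
    derivation, per-SNP association scans with locus-window extension, and a
    synthetic-data generator producing genotype-covariate-mediator-outcome
    datasets under each causal model for fully reproducible desk-scale
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
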