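Package: mrbiome
Title: Two-Sample Mendelian Randomization for Microbiome-Disease Causal Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for bidirectional two-sample Mendelian randomization
    of gut-microbiota abundances (exposures) on a binary disease outcome from GWAS
    summary statistics. Covers instrument selection (p-value thresholding, greedy LD
    clumping, confounder exclusion, F-statistic weak-instrument filtering), allele
    harmonization with palindromic-SNP exclusion and LD proxies, inverse-variance
    weighted, MR-Egger and weighted-median causal estimators, sensitivity diagnostics
    (Cochran's Q, Egger intercept, MR-PRESSO, leave-one-out with Cook's distance),
    and Bayesian model averaging over candidate exposures with MIP/MACE ranking,
    per-SNP outlier diagnostics and permutation p-values. A synthetic summary-statistic
    generator with known ground truth makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'instruments.R'
    'harmonize.R'
    'bma.R'
    'estimators.R'
    'summary-io.R'
    'simulate.R'
    'sensitivity.R'
    'pipeline.R'
    'report.R'
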