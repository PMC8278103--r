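Package: gcablup
Title: Genomic Prediction of Hybrid Performance with GCA/SCA Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-cross hybrid breeding analysis: marker quality
    control and naive imputation, VanRaden/Endelman-Jannink genomic
    relationship matrices, expected F1 hybrid genotypes, Kronecker-product
    specific-combining-ability kernels, and squared difference in parental
    allele frequency (SDAF). The statistical core is a restricted maximum
    likelihood (REML) mixed-model engine built on Henderson's mixed-model
    equations with average-information updates and arbitrary random-effect
    covariance kernels, yielding BLUPs/GBLUPs with prediction error
    variances. On top of it the package provides entry-mean and narrow-sense
    heritability for unbalanced randomized complete block designs,
    PEV-based reliability and selection accuracy, ten-fold male-GCA
    cross-validation, training-set hybrid cross-validation stratified by
    parental membership (T0/T1F/T1M/T1/T2), mid-parent heterosis,
    commercial relative performance, and SDAF-heterosis correlation tests.
    A synthetic-population generator emulates a two-pool hybrid rice
    breeding program (CMS/TGMS female testers crossed to backcross
    introgression male lines) so the whole pipeline runs and is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    vcfR,
    yaml
Config/testthat/edition: 3
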