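Package: huskgs
Title: Genomic Selection and Structure-Aware Cross-Validation for Inbred Panels
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genomic prediction for structured inbred panels: genotype loading
    and quality control (VCF and plain dosage matrices, minor-allele-frequency
    filtering, per-marker mean imputation), VanRaden genomic relationship
    matrices and marker-derived principal components, restricted maximum
    likelihood (REML) variance components and narrow-sense heritability via a
    spectral single-kernel mixed model, genomic best linear unbiased prediction
    (gBLUP), comparison of marker-assisted selection against principal-component
    and kinship-based predictors, and cross-validation schemes that respect
    subpopulation structure (whole-panel, within-subpopulation, and
    across-subpopulation designs). A simulator generates structured inbred
    panels with controlled differentiation and replicated multi-environment
    polygenic traits with known ground truth, so every stage of the pipeline is
    verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
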