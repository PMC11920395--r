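Package: varintol
Title: Ancestry-Aware Genic and Sub-Genic Intolerance Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes genic and sub-genic intolerance metrics from
    ancestry-stratified exome variant catalogs: a mutability-anchored
    Residual Variation Intolerance Score (RVIS) based on studentized
    regression residuals of common functional variant counts on genic
    mutability; gene-level and 31-codon sliding-window Missense Tolerance
    Ratios (MTR) with saturation enumeration of possible single-nucleotide
    substitutions; loss-of-function observed/expected ratios with one-sided
    binomial exact tests and Benjamini-Hochberg correction (LOF-FDR); and a
    benchmarking harness (logistic-regression AUC-ROC, DeLong's test,
    balanced down-sampled variant-level AUC). A synthetic multi-ancestry
    cohort generator with planted intolerant genes makes the full pipeline,
    including the ancestral-diversity versus sample-size comparison,
    reproducible without access-restricted biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    pROC,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
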