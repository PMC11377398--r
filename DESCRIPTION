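Package: cohortsieve
Title: Detecting Genetically Outlying Samples in Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and removing genetically outlying samples
    from case-control sequencing cohorts. Implements a two-stage procedure:
    an annotation-guided sparse neural network (variants grouped into gene
    nodes feeding a logistic output) is first trained on the full cohort and
    scored on the training samples themselves; per-sample ensemble scores,
    combined with disease prevalence and clinically reported misdiagnosis
    rates, then drive the exclusion of likely mislabelled cases and controls
    before the model is retrained and evaluated on stratified splits.
    Includes supporting variant-level quality control for multi-sample VCFs,
    chi-squared genotype association screening, over-representation analysis
    of prioritised genes, and a liability-threshold cohort simulator with
    injectable label noise for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
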