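Package: ryeco2
Title: Intraspecific CO2-Response Analysis for Ryegrass: A-Ci Fitting,
    Whole-Plant Traits, and Trait Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing intraspecific variation in ryegrass
    (Lolium) productivity under ambient and elevated CO2. Implements the
    Farquhar-von Caemmerer-Berry (FvCB) model of C3 photosynthesis with
    Arrhenius temperature scaling, automated two-phase A-Ci curve fitting
    (leak correction, triose-phosphate-use point exclusion, exhaustive
    transition-point search with exact per-split least squares), derived
    whole-plant traits (LMA, leaf area per tiller, whole-plant carbon
    gain, water-use efficiency), a hierarchical synthetic-data generator
    emulating a genotype x treatment x chamber growth-room design, a
    mixed-model inference pipeline (treatment and status comparisons with
    a robust-fallback decision tree, ANCOVA with marginal and conditional
    R2, rank concordance, Spearman correlograms, incremental-R2 predictor
    attribution, germination tests), and validated Ward hierarchical
    clustering of genotype trait matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    lme4,
    lmerTest,
    car,
    lmtest,
    sandwich,
    emmeans,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lhs,
    mclust,
    withr
Config/testthat/edition: 3
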