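Package: neosepsig
Title: Immune-Signature Screening and Rule-Out Diagnostics for Sepsis in
    Very Preterm Infants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal immune-profiling studies of
    late-onset sepsis in very preterm babies. Provides a seeded synthetic
    longitudinal cohort generator (weekly flow-derived immune parameters,
    plasma C-reactive protein and amphiregulin, injected sepsis episodes with
    acute suppression and rebound), rule-based clinical sample classification
    into five categories with episode deduplication, a rank-based
    multi-parameter volcano screen with Benjamini-Hochberg control plus
    age-bracket, age-strata and CRP-stratified analyses, temporal
    pre/sepsis/post paired testing, mixed-model confounder adjustment,
    combined CRP/amphiregulin rule-out test evaluation (ROC, Youden
    threshold, confusion metrics, prevalence-adjusted predictive values), and
    post-processing of per-gene differential-expression tables (fixed gene
    filters, thresholding, multi-condition set partition).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    lmerTest,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
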