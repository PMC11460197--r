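Package: hepplasma
Title: Batch-Aware Differential and Network Analysis of Heparin-Enriched
    Plasma TMT Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis pipeline for multiplexed (TMT) plasma
    proteomics with heparin-affinity enrichment, designed around two-cohort
    Alzheimer's disease case/control studies. Provides channel-sum
    normalization, missingness filtering, global-internal-standard anchored
    two-way median polish batch harmonization, non-parametric bootstrap
    covariate regression, per-set Student's t differential abundance with
    Benjamini-Hochberg control, Fisher meta-analysis across cohorts,
    biomarker-trait correlation, projection of proteins onto consensus brain
    co-expression modules via biweight midcorrelation (kME), one-tailed
    Fisher exact over-representation with standardized Z-scores, and
    logistic-panel ROC classification with DeLong confidence intervals and
    tests. A seeded synthetic-data generator emulating the two-set,
    multi-batch study design with known ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
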