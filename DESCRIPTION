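Package: tp53sig
Title: TP53 Gene-Expression Signature Scoring and Prognostic Analysis for Breast Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes the ratio-based TP53 signature score from a 26-gene
    multiplex expression panel (16 genes up-regulated and 7 down-regulated in
    TP53-mutant tumours, plus 3 internal controls), classifies samples as
    TP53 mutant- or wild-type-signature at a published cutoff, calibrates the
    cutoff by ROC analysis against a reference TP53 status, and reproduces the
    downstream prognostic workflow: Kaplan-Meier curves, log-rank tests,
    univariate and multivariate Cox proportional-hazards models for
    recurrence-free, overall and breast-cancer-specific survival, molecular
    subtype and grade stratification, and baseline-characteristics testing.
    Includes a synthetic-cohort simulator with the class balance, covariate
    structure and proportional-hazards event process the analysis assumes, so
    every pipeline stage is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    SummarizedExperiment,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
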