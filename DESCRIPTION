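Package: claimrisk
Title: Multimodal Neural Survival Models for Comorbidity Risk from
    Longitudinal Claims Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds time-aware comorbidity risk models from coded
    administrative claims histories. Provides cohort construction from
    longitudinal diagnosis and prescription event tables (inclusion rule
    engine, index dates, history/follow-up filters, incident-case survival
    labelling), knowledge-based feature augmentation through pluggable
    code-mapping tables, monthly binning into multimodal patient data
    cubes, a multimodal bottleneck neural network trained with a Cox
    partial-likelihood loss under groupwise elastic-net regularization,
    Breslow baseline hazards and survival curves, inverse probability of
    censoring weighted concordance evaluation (Harrell's C, Uno's C,
    time-dependent AUC), Bayesian hyperparameter search with nested
    cross-validation, Shapley-value model explanation, and a synthetic
    claims simulator with planted proportional-hazards ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
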