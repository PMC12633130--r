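Package: hnctwin
Title: Generative Digital Twin for Sequential Treatment of Oropharyngeal Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A generative patient digital twin for oropharyngeal squamous cell
    carcinoma treatment. Couples a heterogeneous-data variational autoencoder,
    which learns and samples pre-treatment patient profiles (demographics,
    staging, baseline MDASI-HN symptom scores), with a chain of gradient-boosted
    predictors that forecast post-intervention outcomes, symptom trajectories,
    and three-year relapse, conditional on first-cycle treatment actions
    (definitive surgery, induction chemotherapy, radiotherapy with or without
    concurrent chemotherapy). Includes a synthetic-cohort generator
    parameterised from published demographic tables, event-log timeline
    simplification and treatment-sequence mining, per-feature Wasserstein
    fidelity evaluation, macro-F1/MSE benchmarking against median/mean, random,
    and multilayer-perceptron baselines, and a three-step sequential decision
    environment for what-if treatment-plan comparison.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
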