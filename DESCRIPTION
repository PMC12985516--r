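Package: npcnodes
Title: Paired Diagnostic Accuracy, N-Staging and Cost-Effectiveness of
    Nodal Imaging in Nasopharyngeal Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating two imaging modalities (FDG PET/CT and
    MRI) against a pathology reference standard for cervical lymph node
    assessment in nasopharyngeal carcinoma. Provides paired node-level
    diagnostic accuracy comparison (confusion matrices at an ordinal score
    cutoff, Wilson confidence intervals, McNemar and weighted generalized
    score tests, DeLong comparison of correlated AUCs), patient-level
    TNM N-stage assignment and biopsy adjudication with upper-neck-only
    irradiation eligibility, tabulation of radiotherapy decision changes,
    and a decision-tree plus Markov cohort cost-effectiveness model
    comparing MRI-first and PET/CT-first staging strategies, with
    deterministic (tornado) and probabilistic sensitivity analyses.
    Includes exact fixture generators and a stochastic paired-cohort
    simulator so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
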