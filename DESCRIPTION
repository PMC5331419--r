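Package: arqsar
Title: QSAR Modelling and Virtual Screening for Steroidal Androgen
    Receptor Antagonists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates multiple-linear-regression QSAR models for
    7-alpha-substituted dihydrotestosterone androgen-receptor antagonists.
    Provides descriptor curation (constant and near-constant removal,
    pairwise-correlation pruning), genetic-algorithm descriptor-subset
    selection scored by the Friedman lack-of-fit statistic, internal and
    external validation (R2, leave-one-out and leave-many-out Q2, Q2F1/F2/F3,
    Lin's concordance correlation, Y-scrambling), a leverage-based
    applicability domain with Williams-plot and Insubria-graph outputs,
    virtual-screening prediction and ranking with a frozen model, MM/GBSA
    binding-free-energy bookkeeping, and a synthetic descriptor-table
    generator so every stage is testable without proprietary descriptor
    software. Ships the reference activity table, published four-descriptor
    model, screening predictions, and energy-term tables for the
    dihydrotestosterone antagonist series as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
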