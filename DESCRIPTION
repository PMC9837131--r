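Package: spfa
Title: Supervised Poisson Factor Analysis for Patient Subphenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weakly supervised topic modelling of binary patient-by-feature
    matrices built from electronic health records. Fits a supervised Poisson
    factor analysis model with a Gamma shrinkage prior on topic weights, an
    amortized Weibull variational posterior, and a logistic outcome head on
    the latent topic weights, trained by stochastic gradient variational
    inference. Includes a longitudinal cohort builder (index dates, baseline
    and follow-up windows, serious-adverse-event labels), k-means
    subphenotyping with silhouette-based model selection, topic triage by
    mean topic weight and Mann-Whitney U tests, NPMI topic coherence,
    contingency-table trait screening, and a synthetic-cohort generator so
    that the full pipeline is testable without access to protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    cluster,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
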