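Package: proteoload
Title: Proteome-Wide Survival Association and Mendelian Randomization for
    APOE-Dependent Protein Signatures of Incident Alzheimer's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A staged analysis pipeline for serum-proteomic studies of incident
    late-onset Alzheimer's disease (LOAD): Box-Cox preprocessing of aptamer-based
    protein matrices, proteome-wide Cox proportional-hazards and logistic
    association scans under nested covariate models, classification of protein
    signatures into APOE-e4-dependent and -independent components,
    mediation-by-adjustment of the e4 effect, bidirectional two-sample Mendelian
    randomization with correlated cis-pQTL instruments (generalized weighted
    least squares, inverse-variance weighting, Wald ratio, Cochran's Q,
    MR-Egger), and enrichment and sign-concordance statistics. Ships a seeded
    synthetic cohort generator emulating the statistical structure of an elderly
    population-based cohort so every stage is testable without access to
    individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
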