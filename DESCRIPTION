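Package: cmlkinetics
Title: Early Prediction of Deep Molecular Response in Chronic Myeloid Leukemia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the decline of BCR-ABL1-positive leukemic cells and the
    recovery of normal white blood cells in chronic myeloid leukemia patients
    on tyrosine kinase inhibitor therapy as a pair of linear first-order
    kinetics fitted to longitudinal WBC and international-scale (IS)
    transcript measurements. Provides a penalized cohort-level fit sharing an
    ABL1 expression ratio across patients, a closed-form three-visit estimator
    of the leukemic reduction rate and plateau, a threshold-region classifier
    with leave-one-out cross-validation that predicts deep molecular response
    (MR4.0/MR4.5/CMR) from the first three clinic visits, baseline prognostic
    score comparators (EUTOS, ELTS, ELN milestone staging), and a synthetic
    cohort generator with detection-limit censoring for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
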