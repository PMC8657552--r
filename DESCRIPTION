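Package: sesvm
Title: Sensitivity Evaluation with Support Vector Machines for
    Regional Environmental-Health Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying how climate variables
    and regional eco-efficiency relate to population health outcomes in
    regional panel data. Computes eco-efficiency scores with the
    slacks-based-measure (SBM) data envelopment analysis model with
    undesirable outputs, fits least-squares support-vector regression
    (LS-SVR) with a radial-basis-function kernel via its closed-form dual
    solution, tunes the kernel width and regularization weight with a
    random direct search, evaluates in-sample forecasts with mean
    percentage error, mean squared error and its square root, and
    measures elasticities of the fitted response by one-at-a-time 1%
    perturbation of each predictor. A synthetic panel generator with
    known ground-truth elasticities supports validation throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
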