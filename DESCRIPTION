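Package: poolvar
Title: Blending-Error Variance Components for Pooled RNA Expression Designs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Per-transcript linear mixed models for gene expression
    experiments in which RNA from several individuals is blended into
    pools of variable size. Imperfect blending of aliquots induces a
    technical variance component beyond the usual biological and
    residual variances; the package builds the corresponding design and
    covariance matrices from a declarative pool design, estimates the
    three variance components by EM-REML through Henderson's mixed model
    equations, tests the blending component with a boundary-corrected
    residual likelihood ratio test, tests treatment contrasts with
    Kenward-Roger adjusted F-tests, and controls the false discovery
    rate with Storey's bootstrap pi0 and q-values. A simulation module
    generates pooled one-color experiments with Dirichlet aliquot
    weights and full ground truth, and a study pipeline reproduces the
    model-comparison summaries of such simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
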