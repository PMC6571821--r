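Package: tripls
Title: Bilinear and Trilinear PLS Models for Variable Selection in
    Intervention Time-Series Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for biomarker (variable) selection in metabolomic
    intervention studies with a time-series design. Implements five partial
    least squares (PLS) modelling strategies combining bilinear (sample x
    metabolite) or trilinear (subject x metabolite x time) predictor
    structure with group, time-response, or combined dummy responses;
    tri-PLS1/tri-PLS2 (N-PLS) fitting; centring, autoscaling and
    single-slab scaling; cross-validated latent-variable selection;
    balanced-bootstrap VIP (variable importance in projection) statistics
    with an uncertainty-aware selection rule; a parametric simulator of
    intervention time-series with known discriminating variables; and an
    evaluation framework (variable-selection ROC, recall/precision/F1,
    Q2, ROC AUC, permutation test) for benchmarking the five models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
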