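Package: contestRHP
Title: Inference of Group Resource Holding Potential from Dyadic Intergroup Contests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying which group- and individual-level
    properties predict victory in dyadic intergroup contests between
    social-animal groups (group resource holding potential proxies),
    built around the analysis design used for long-term banded mongoose
    field data. Implements truncated-normal imputation of missing
    pre-contest weights, relative (focal minus rival) predictor
    construction, binomial/Poisson/Gaussian mixed models with crossed
    random intercepts fitted by a Laplace-approximate likelihood,
    all-subsets AICc multimodel inference with a nesting rule and model
    averaging, an iterated imputation-by-model-selection loop with
    percentile aggregation, a Bayesian contest model constraining focal
    and rival group effects to be equal and opposite, and the follow-up
    analyses (sexual dimorphism, senior-male age effects, repeatability,
    eviction and paternity models). Includes a synthetic-data generator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
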