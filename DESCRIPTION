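Package: blendRSA
Title: Semantic Blend Constraint Metrics and Spatiotemporal Searchlight RSA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the incremental semantic constraint a spoken sentence
    context places on upcoming words and tests those models against
    source-space electrophysiological data. Builds topic representations of
    words from syntactically sliced co-occurrence counts (local mutual
    information weighting and a seeded collapsed Gibbs LDA sampler), turns
    sentence-completion norms into probabilistic semantic "blends",
    summarizes each blend by dispersion-corrected entropy or by cosine
    mismatch with the heard word, and relates the resulting per-trial
    metrics to trials-by-vertices-by-time source epochs with a
    spatiotemporal searchlight representational similarity analysis:
    rank-based partial Spearman model fits with nuisance covariates
    partialled out, one-sample group t-maps, and cluster-level inference by
    sign-flip permutation of subject maps with a maximum cluster-mass null.
    A fully seeded synthetic-data generator emulates every required input
    (stimuli, completion norms, block-structured co-occurrence corpora, and
    source epochs with a controllable injected representational effect) so
    the whole pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
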