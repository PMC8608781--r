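Package: wsbm
Title: Weighted Stochastic Block Models with Gamma Edge Weights
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits directed weighted stochastic block models in which edge
    existence is Bernoulli and the weight of an existing edge follows a
    gamma distribution whose shape and rate depend on the latent blocks of
    the two endpoints. Estimation uses mean-field variational EM with
    closed-form moment-based updates for the gamma parameters, and the
    number of blocks is chosen with an approximate integrated completed
    likelihood (ICL) criterion. Includes a generative sampler, exact
    likelihood evaluation by enumeration for small graphs, permutation
    alignment of block labels, a simulation harness for parameter-recovery
    and model-selection experiments, and readers/writers for weighted edge
    lists, dense matrix pairs and Matrix Market files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
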