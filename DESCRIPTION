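Package: BoolContext
Title: Contextualization of Prior Knowledge Networks into Asynchronous
    Boolean Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds context-specific asynchronous Boolean models as
    sub-networks of a signed prior knowledge network (PKN). A genetic
    algorithm searches edge subsets of the PKN for networks whose
    attractors and attractor-to-attractor transitions under perturbation
    reproduce a training set of stable phenotypes, using a lexicographic
    multi-objective fitness. Includes exact (terminal strongly connected
    component) and stochastic attractor engines for the asynchronous
    state transition graph, an in-silico benchmarking workflow that
    derives PKNs and training sets from a gold-standard network with
    configurable noise and error injection, a predictive-power score
    comparing model and gold-standard responses to all single-node
    perturbations, and combined-prediction error-versus-variance
    analysis across model ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
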