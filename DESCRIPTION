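Package: mplexvar
Title: Differential Node-Neighborhood Analysis of Two-Layer Multiplex Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies, for every node of a two-layer weighted multiplex
    network, how much its local neighborhood differs between the layers, by
    jointly embedding all layers with an encoder-decoder neural network and
    measuring per-node between-layer distances in the shared embedding space.
    Statistical significance is assessed either against embedded
    permutation-null networks (two-condition comparison) or by association of
    per-individual distances with a phenotype (cohorts of individual-specific
    networks built with LIONESS). Includes gene co-expression network
    construction from expression matrices, planted-perturbation simulation
    utilities, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
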