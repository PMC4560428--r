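Package: ccgrn
Title: Boolean and Continuous Dynamics of the Arabidopsis Cell-Cycle
    Gene Regulatory Network
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Synchronous Boolean network dynamics for gene regulatory
    network models, with exhaustive attractor and basin-of-attraction
    enumeration, truth-table and state-transition bit-flip robustness
    analyses, structure-matched random network ensembles, in-silico
    loss- and gain-of-function (node clamping) mutant simulation, and a
    fuzzy-logic continuous (ODE) approximation of the logical model.
    Ships a 14-node model of the Arabidopsis thaliana cell cycle that
    converges to a single period-11 limit-cycle attractor spanning the
    G1, S, G2 and M phases, together with the mutant phenotype
    expectations used to validate it.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    deSolve,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
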