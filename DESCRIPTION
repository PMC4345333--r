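Package: exforce
Title: Expected Force of Infection and Node Spreading Power on Contact Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the expected force (ExF), an entropy-based measure of
    node spreading power derived from the force of infection generated over
    all enumerated two-transmission clusters around a seed node, together
    with its degree-corrected variant, comparator centralities (k-shell,
    eigenvector centrality), event-driven continuous-time and synchronous
    discrete-time SI/SIS/SIR epidemic simulators, transmissibility
    calibration by binary search on the epidemic-potential criterion,
    Chung-Lu scale-free and degree-sequence network generators, and a
    benchmarking harness that correlates node metrics with simulated
    epidemic outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
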