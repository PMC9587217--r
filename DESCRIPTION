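Package: micromod
Title: Micro-Scale Functional Module Analysis for Microelectrode Array
    Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and validating micro-scale functional
    modules in multichannel microelectrode recordings. Builds weighted
    directed functional networks from local field potentials via pairwise
    conditional Granger causality (time-domain and Geweke spectral
    decomposition with Wilson spectral factorization), partitions the
    resulting temporal multilayer networks with generalized Louvain
    modularity maximization, quantifies module persistence, stationarity
    and spatial geometry (radius of gyration, convex-hull compactness),
    builds degree-matched directed surrogate ensembles, and validates
    modules functionally with cross-validated population spike decoding
    under shuffle-within / shuffle-across and distance-matched boundary
    controls. Includes a synthetic-session generator (modular vector
    autoregressions with frequency-specific coupling and module-tuned
    Poisson spiking) with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    pracma,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
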