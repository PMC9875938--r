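Package: simonEEG
Title: Simulation and Concatenated Decomposition-Decoding Analysis of
    Simon Go/Nogo EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for simulating epoched multi-channel EEG from a Simon-type
    Go/Nogo conflict task with known ground truth, and for a concatenated
    analysis chain on such data: zero-phase band-pass filtering, resampling,
    automated artifact rejection, spherical-spline current source density,
    residue iteration decomposition (RIDE) into stimulus-locked (S) and
    latency-variable (C) component clusters, group spatial ICA with subject
    back-reconstruction and rank-1 back-projection, correlation-based matching
    of component topographies across conditions, time-resolved and
    temporal-generalization multivariate decoding with cluster-based
    sign-flip permutation statistics, a standardized minimum-norm (sLORETA)
    inverse on a simulated lead field with nonparametric max-statistic
    condition contrasts, and behavioural summaries with paired tests and
    effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    MASS,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
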