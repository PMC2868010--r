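Package: dfmalign
Title: Dynamics-Based Alignment of Proteins via Distance-Fluctuation Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes protein backbone dynamics by the Dynamic Fingerprint
    Matrix (DFM), the matrix of standard deviations of inter-residue C-alpha
    distances over a conformational ensemble, and aligns two proteins using
    only their DFMs. Alignment quality is scored by a logistic pairwise match
    score over equivalent matrix entries; the optimal monotone alignment is
    searched by multiple-restart simulated annealing with a compiled Metropolis
    core; significance of dynamic similarity scores is assessed against a
    size-calibrated type I extreme value (Gumbel) null model. Includes readers
    for multi-model PDB files, DCD trajectories and a plain-text ensemble
    dialect, an elastic-network-style synthetic ensemble generator with planted
    homology for validation and null calibration, and an all-versus-all batch
    driver producing score and p-value matrices and a dynamic-similarity graph.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
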