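Package: vibnqs
Title: Modal-Backflow Neural Quantum States for Anharmonic Vibrational
    Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Variational solution of second-quantized Watson Hamiltonians
    on truncated bosonic Fock spaces with modal-backflow neural quantum
    states. Provides construction of Watson operators from quartic-to-sextic
    force fields (with optional Coriolis coupling), a random force-field
    sampler spanning weak to strong anharmonicity, modal-product and
    feedforward-network amplitude ansaetze, a deterministic
    selected-configuration scheme for energies and gradients, the CoRe
    adaptive optimizer, vibrational self-consistent-field pretraining, a
    penalty-shifted excited-state ladder, and a sparse
    exact-diagonalization reference for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
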