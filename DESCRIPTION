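Package: huzembed
Title: Open-Shell Projection-Based Embedding with the Huzinaga Equation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multilevel quantum-chemical calculations for open-shell molecules
    using projection-based embedding (PbE) built on the Huzinaga equation.
    Provides spin-unrestricted (UHF/UKS) and restricted open-shell
    (ROHF/ROKS, Roothaan ensemble formalism) self-consistent field solvers,
    SPADE and Mulliken-population orbital partitioning, embedded-subsystem
    reoptimization in the frozen potential of the environment with
    first-order-corrected multilevel energies, mixed
    restricted/unrestricted embedding schemes, and ONIOM/vacuum baseline
    models with link atoms and point-charge electronic embedding. A compact
    native engine supplies Gaussian integrals (McMurchie-Davidson, s/p
    shells), Becke-grid LDA/PBE/PBE0 exchange-correlation, and canonical
    MP2 correlation for desk-scale molecules.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
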