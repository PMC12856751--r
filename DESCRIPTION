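Package: vqepdft
Title: Quantum-Classical Hybrid Electronic Structure with Pair-Density
    Functional Theory and Marcus Electron-Transfer Rates
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A simulated quantum-classical hybrid workflow for strongly
    correlated active spaces. A statevector quantum-circuit engine solves the
    CASCI active-space Hamiltonian variationally (UCCSD, restricted open-shell
    UCCSD, or shallow particle-conserving hardware-efficient circuits built by
    a greedy symmetry-guided synthesis), one- and two-particle reduced density
    matrices are extracted exactly or by simulated shot measurement with
    readout-error mitigation, and the total energy is assembled classically
    with a translated-PBE on-top pair-density functional. A Marcus layer turns
    four-point energy tables into reorganization energies, driving forces,
    Boys-localized electronic couplings and nonadiabatic transfer rates, with
    ensemble averaging and a noise-propagation study of error cancellation in
    energy differences. Includes a Gaussian-integral engine (McMurchie-
    Davidson), restricted and restricted open-shell Hartree-Fock, parity
    fermion-to-qubit mapping with two-qubit symmetry tapering, and qubit-wise
    commuting measurement grouping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rhdf5,
    optparse
Config/testthat/edition: 3
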