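Package: qneo
Title: Quantum Circuit Simulation of Nuclear-Electronic Orbital Proton Transfer
Version: 0.1.0
Authors@R:
    person("qneo", "maintainers", email = "qneo@example.org", role = c("aut", "cre"))
Description: End-to-end simulation pipeline for proton-transfer kinetics with a
    quantum-mechanically treated proton in the nuclear-electronic orbital (NEO)
    framework. Provides a data model and text serializations for coupled
    electron-proton second-quantized Hamiltonians, convex interpolation along a
    Left/Middle/Right reaction trajectory, Loewdin orthogonalization and frozen
    natural orbital truncation, Jordan-Wigner qubit mapping, exact CASCI sector
    diagonalization with reduced density matrices and proton-electron
    entanglement entropy, ADAPT-VQE state preparation over the NEO excitation
    pool, adaptive approximate quantum compiling of the resulting circuits into
    shallow two-qubit-block circuits, device-style noisy simulation with gate
    folding and zero-noise extrapolation of barrier heights, and Eyring-type
    transition-state-theory rate constants with barrier-error sensitivity
    analysis. Includes seeded synthetic double-well model generators for
    testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
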