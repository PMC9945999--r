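Package: quenchsep
Title: Marcus-Theory Analysis of Chlorophyll Fluorescence Concentration
    Quenching via Photoinduced Charge Separation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs quadratic free-energy surfaces for the photoexcited
    and charge-separated states of closely spaced chlorophyll pairs from
    sampled vertical energy gaps (linear response), evaluates Marcus-theory
    electron-transfer rate constants with confidence-interval propagation,
    models the exponential distance decay of the donor-acceptor coupling,
    diagonalizes Frenkel exciton Hamiltonians built from atomic transition
    charges, assembles point-charge electrostatic energies for monomer-based
    QM/MM decompositions, and estimates the concentration-dependent fraction
    of statistical chromophore pairs. Includes a seeded synthetic-trajectory
    generator emulating the statistical structure of molecular-dynamics
    energy-gap samples so the full pipeline is testable without raw
    trajectory data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
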