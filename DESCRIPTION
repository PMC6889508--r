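Package: relaxfit
Title: Stopped-Flow Relaxation Kinetics and Equilibrium Binding Analysis
Version: 0.1.0
Authors@R: person("relaxfit", "developers", role = c("aut", "cre"),
    email = "relaxfit@example.org")
Description: Simulation and global fitting of stopped-flow relaxation
    transients for ligand binding to trypsin-like proteases under
    conformational-selection and lock-and-key mechanisms, with Arrhenius
    temperature parameterization of the rate constants and derivation of
    binding thermodynamics (Kd, free energy, enthalpy, entropy).  Also
    provides two-state chemical-denaturation fitting (midpoint and m-value
    with linear baselines) and hyperbolic equilibrium titration fitting for
    monovalent-cation binding, plus seeded synthetic-data generators that
    stand in for the instrument, file readers/writers for trace and curve
    data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
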