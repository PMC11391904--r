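Package: namdnet
Title: Neural-Network Potentials and Surface-Hopping Dynamics for Excited States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for machine-learned excited-state molecular dynamics: multi-state
    message-passing neural network potentials (rotationally invariant and equivariant)
    predicting energies, forces, smoothed nonadiabatic coupling vectors and dipole
    moments; phase-free loss functions that tolerate the arbitrary wavefunction sign of
    coupled-state properties; fewest-switches surface hopping driven by trained models;
    Franck-Condon absorption spectra from transition dipoles; and analytic diabatic
    model Hamiltonians (avoided crossings, conical intersections) that supply exact
    reference data for training and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
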