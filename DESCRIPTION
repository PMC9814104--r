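Package: tvakit
Title: Transient Vibrational Absorption Decomposition and Photoisomerization Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis chain for ultrafast pump-probe infrared studies of
    E/Z photoswitches such as sinapate esters: fixed-shape spectral
    decomposition of transient vibrational absorption maps into
    ground-state-bleach, vibrational-relaxation and photoisomer components;
    mono-exponential kinetic fitting with bootstrap uncertainties and
    ground-state-bleach percentage recovery; two-state photokinetics with
    analytic photostationary state and quantum-yield estimation from
    irradiation series; a conical-intersection exit branching-tree model for
    predicted isomer yields; first-order branching-plane topography
    classification (peaked/sloped, single-path/bifurcating); harmonic
    line-list scaling and vibrational band assignment; and seeded synthetic
    data generators that emulate all of the above experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    deSolve,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
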