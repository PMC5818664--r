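Package: permeon
Title: Ion Permeation Analysis for Computational Electrophysiology
    Trajectories
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for double-membrane ("computational
    electrophysiology") ion-channel permeation simulations, built around the
    NaK channel. Provides a channel-centric coordinate system and region
    model, permeation-event detection with axial versus side-entry pathway
    classification, conversion of event counts to currents and conductances,
    membrane-potential profiles by double integration of the charge density
    (Poisson equation), ion occupancy and potential-of-mean-force surfaces by
    Boltzmann inversion, hydration and coordination-shell analysis, and
    selectivity-filter carbonyl-flip conformer diagnostics (opposing-carbonyl
    distances, hydrogen-bond networks, amide-proton contact maps). A kinetic
    synthetic-trajectory generator with planted ground truth stands in for
    microsecond-scale molecular dynamics runs and drives the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    data.table,
    jsonlite,
    pracma,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
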