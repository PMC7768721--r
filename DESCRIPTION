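Package: natzamx
Title: Reaction-Transport Modelling and Bioenergetics of Anammox in the
    Nitrate-Ammonium Transition Zone of Marine Sediments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying anaerobic ammonium oxidation (anammox) in
    the nitrate-ammonium transition zone (NATZ) of marine sediments. Provides
    a one-dimensional finite-volume steady-state reaction-transport model of
    porewater chemistry (O2, NO3-, NH4+, Mn2+, DIC, TOC, MnO2) with a
    six-reaction diagenetic network; in-situ Gibbs free energy and catabolic
    power-supply profiles for anammox with cell-specific rate and
    proton-pumping conversions; quality filtering, transition-zone detection,
    Fickian diffusive-flux estimation and efflux classification for
    multi-site porewater profile compilations; an index-of-replication (iRep)
    estimator from per-window genome coverage; and seeded synthetic-data
    generators that emit ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
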