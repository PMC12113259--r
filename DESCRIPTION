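Package: optoRhoA
Title: Minimal Model of Optogenetic GEF Recruitment and RhoA/Cdc42 Phenotype Switching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and fits a minimal kinetic model of optogenetically
    recruited PDZ-RhoGEF (optoPRG), in which the GEF both activates RhoA and,
    via its PH domain, sequesters RhoA-GTP into a signaling-dead complex while
    also activating Cdc42. Provides pulse-train stimulus generation with
    iLID/SspB dark-state off-kinetics, a quasi-steady-state ODE for free
    active RhoA driven by measured or synthetic GEF recruitment curves, a
    first-order relocation-biosensor layer, the un-approximated mass-action
    system as a numerical oracle, per-cell least-squares estimation of the
    single free parameter Geq/Kb and of the shared rates (k2, sensor koff),
    a bounded phenotype score gamma with weight calibration, phenotype maps
    over expression level and pulse frequency, a seeded synthetic-data
    generator emulating single-cell microscopy cohorts, and mask-based trace
    quantification (biosensor normalization, surface displacement,
    persistence).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    signal,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
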