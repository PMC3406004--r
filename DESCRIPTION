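Package: cocainePK
Title: Two-Compartment Pharmacokinetics of Cocaine with Michaelis-Menten
    Elimination and Enzyme-Therapy Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and calibrates a two-compartment (plasma/brain)
    pharmacokinetic model of cocaine in which plasma elimination follows
    Michaelis-Menten kinetics of a cocaine-hydrolysing enzyme. Provides
    stiff-capable simulation of the coupled concentration equations,
    exposure metrics (trapezoidal AUC, AUC to infinity with exponential
    tail correction, peak concentration and time, brain half-life),
    least-squares calibration of the transfer and volume parameters with
    multi-start optimisation and a numerical identifiability probe, a
    registry of cocaine-metabolising enzymes (wild-type BChE, CocE,
    CocH1-3), threshold-of-effect estimation from dopamine-transporter
    occupancy calibration doses, and a search for the maximum plasma
    concentration a given enzyme dose can keep below threshold in brain.
    A synthetic-data generator emulates PET-like paired plasma/brain
    time courses with known ground truth for testing calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
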