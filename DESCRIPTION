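Package: fueldrops
Title: Kinetics and Phase Behaviour of Chemically Fueled Peptide-RNA
    Coacervate Droplets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models and analyses fuel-driven complex coacervation between a
    cationic peptide and RNA. Implements the five-species carbodiimide (EDC)
    reaction-cycle ODE model and its characteristic times, calibration of the
    rate constants against HPLC time courses, the benzylamine-quench delay
    correction for filtrate measurements, one-site (Wiseman) fits of ITC
    binding isotherms, phase-regime classification with two-phase mass
    balances and charge ratios, turbidity lifetimes, droplet segmentation and
    partition-coefficient estimation in fluorescence micrographs, and seeded
    synthetic-data generators for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
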