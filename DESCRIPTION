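Package: pulseoxmc
Title: Monte Carlo Simulation of Pulse-Oximeter Signal Strength in a
    Layered Head Phantom
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Weighted photon-packet Monte Carlo transport through a
    three-layer (skin, skull, brain) head phantom containing a cylindrical
    pulsatile artery, with Henyey-Greenstein scattering, Russian roulette,
    seeded per-packet random-number substreams, and perturbation
    reweighting for small optical-property changes. Includes the analysis
    pipeline that converts artery-diameter sweeps into a reflectance
    pulse-oximeter pulsation amplitude (ppm of injected flux) as a
    function of artery depth, and the instrument-side calibration
    arithmetic of a direct-converting oximeter (photodiode sensitivity,
    area-ratio flux scaling, ADC resolution, ppm normalisation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
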