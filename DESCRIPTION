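Package: fusuq
Title: Focused-Ultrasound Acoustic and Thermal Simulation with Uncertainty Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates focused-ultrasound (FUS) sonications in tissue-mimicking
    gelatin phantoms with a hybrid angular spectrum (HAS) acoustic solver coupled
    to a perfusionless Pennes bioheat (PBHE) finite-difference thermal solver.
    Models the 256-element phased-array source via the Rayleigh-Sommerfeld
    integral with an element response function array (ERFA), emulates the MR
    thermometry (MRTI) measurement chain (frame averaging, resampling, noise,
    drift, replicate averaging), computes focal-profile comparison metrics
    (spatiotemporal peak, transverse/longitudinal FWHM, percent errors), and
    propagates acoustic/thermal property uncertainties by Monte Carlo sampling
    with standardized-regression-coefficient local sensitivity analysis.
    Includes the bench calculations used to characterize phantom media:
    attenuation power-law fits, radiation-force-balance power, insertion-loss
    attenuation, reflection coefficients, and transducer efficiency.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
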