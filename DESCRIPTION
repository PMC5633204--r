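Package: angionorm
Title: Tumor Growth, Vascular Normalization and Liposomal Drug Delivery Simulator
Version: 0.1.0
Authors@R:
    person("Angionorm", "Developers", email = "angionorm@example.org",
           role = c("aut", "cre"))
Description: A two-dimensional continuum simulator of solid-tumor growth
    coupled to angiogenesis, interstitial fluid pressure (IFP) and drug
    transport. Tumor cell and vessel densities evolve by reaction-diffusion
    dynamics with a bistable vessel-island term; interstitial fluid pressure
    obeys a Darcy/Starling elliptic balance with dynamic vessel-wall
    conductivities that switch between leaky (angiogenic) and normalized
    states; antiangiogenic agents and 100 nm liposomal chemotherapy are
    delivered by bolus plasma pharmacokinetics and quasi-steady
    tissue-transport solves (diffusion for the small agent,
    convection-dominated transport for liposomes). A treatment-scheduling
    engine reproduces antiangiogenic/chemotherapy combination regimens, dose
    tapering and calibration to a target microvascular-density reduction, and
    reports drug extravasation, exposure and tumor-burden metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
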