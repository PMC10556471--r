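Package: csiplan
Title: Automated 3D-Conformal Craniospinal Irradiation Treatment Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated treatment planning for pediatric craniospinal
    irradiation (CSI) with 3D-conformal photon fields. Provides parametric
    synthetic pediatric phantoms (density volume plus an 18-structure labeled
    mask set), anatomical compatibility pre-checks (junction feathering space,
    half-beam-block fit, spine field-configuration selection), construction of
    opposed lateral brain fields and posterior-anterior spine fields with
    beam's-eye-view MLC aperture fitting and divergence matching, a simplified
    analytic 6 MV photon dose model, junction feathering with weighted
    sub-plan compositing, coverage-based normalization, and dose-volume
    histogram plan evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
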