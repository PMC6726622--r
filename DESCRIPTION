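Package: protodyn
Title: Proton-Dynamic Therapy Modelling: Bragg-Peak Dosimetry,
    Photosensitiser Photophysics and Differential Cytotoxicity
Version: 0.1.0
Authors@R:
    person("protodyn", "developers", email = "protodyn@example.org",
           role = c("aut", "cre"))
Description: A desk-scale quantitative model chain for proton-dynamic
    therapy experiments: analytic proton depth-dose (Bragg) curves in
    solvents from relativistic Bethe stopping power with Bragg additivity
    and the residual-range method; proton-induced photosensitiser
    fluorescence versus depth, concentration and fluence with an
    extinction-normalised efficiency statistic; type-II singlet-oxygen
    photokinetics with two-pathway photobleaching, photoproduct formation
    and deconvolution; emission-spectrum despiking, background
    subtraction, band decomposition and spectral matching; beam-image
    depth profiling; MTT viability analysis against matched controls with
    a differential proton-dynamic gain statistic; and seeded synthetic
    generators for every input so the full pipeline is testable without
    raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
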