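Package: prpspin
Title: Kinematic-Wave Modelling of Blood Centrifugation for Platelet-Rich
    Plasma Preparation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts plasma, platelet and white-blood-cell recovery rates for
    single-spin centrifugation of whole blood in a tube. Solves the
    one-dimensional kinematic-wave (Kynch) sedimentation equation for the
    centrifugal field with a monotone Engquist-Osher finite-volume scheme on
    flat- or conical-bottom tube geometries, extracts the supernatant and
    sediment interfaces, and converts them to recovery rates. A
    dimensional-analysis (Buckingham-Pi) power-law correlation links platelet
    recovery to plasma recovery and can be refitted to user data by ordinary or
    nonlinear least squares. Protocol-sweep utilities map recovery over spin
    time and centrifugal acceleration, locate critical accelerations, and
    compare tube geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
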