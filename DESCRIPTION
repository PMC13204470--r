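Package: scgtwin
Title: Digital Twin of a Triboelectric Seismocardiography Acquisition Chain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for seismocardiogram (SCG)
    acquisition with a triboelectric chest-wall force sensor. Provides a
    synthetic SCG generator with annotated fiducial events (MC, IM, AO, IC,
    AC, MO), a forward model of the sensor's nonlinear static response and
    asymmetric dynamics plus its analog front end (transimpedance pole,
    third-order Butterworth low-pass, mains notch, high-pass level shift,
    12-bit ADC), beat localization via narrow-band enhancement and sliding
    RMS envelopes, template averaging and fiducial annotation, window-level
    signal quality screening and feature extraction, and three-class
    systolic/diastolic blood-pressure classification with a from-scratch
    softmax multinomial logistic regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    pROC
Config/testthat/edition: 3
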