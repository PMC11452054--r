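Package: gaitlatent
Title: Latent Gait Features from Foot-Worn IMU Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-minute walk tests recorded with
    foot-worn six-axis inertial measurement units (IMUs). Provides a
    synthetic two-foot gait-signal generator with known ground truth, a
    gait-event (foot contact, stance/swing) detector, gait-speed
    estimation via sensor-fusion orientation tracking and zero-velocity
    updates, preprocessing of recordings into normalized 512x6 epochs, a
    convolutional variational autoencoder that reduces each epoch to 12
    latent gait features, measurement-level feature aggregation, and the
    psychometric evaluation of the resulting scores: test-retest
    reliability (ICC(2,1), SEM, MDC), stroke-versus-healthy group
    comparison (t-test, Hedges' g), and MDC-based individual
    responsiveness during rehabilitation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
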