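Package: pulsewave
Title: Dual-Sensor Arterial Pulse-Wave Analysis and Cuffless Blood-Pressure Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing toolchain for dual-channel arterial pulse waves
    recorded by piezoelectric contact sensors. Provides Kaiser-window FIR
    band-pass design and application, dynamic-threshold (hysteresis) pulse
    peak and trough detection, interval-based ectopic beat (PAC/PVC) flagging,
    proximal/distal peak pairing into pulse transit time (PTT) and pulse wave
    velocity (PWV), Moens-Korteweg mean-arterial-pressure estimation, analog
    front-end design calculators, beat-detection scoring, and a seeded
    synthetic dual-channel pulse-wave generator with ground-truth annotations
    so that every stage is testable without patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
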