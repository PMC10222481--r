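Package: seatsense
Title: Uncertainty-Aware Sitting-Posture Asymmetry Detection from a
    Four-Sensor Seat Cushion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hardware-independent implementation of a real-time sitting-posture
    asymmetry monitor based on four force-sensing resistors embedded in a seat
    cushion. Converts raw ADC counts to forces through a voltage-divider
    read-out and a linear conductance calibration, attaches type-B measurement
    uncertainty, low-pass filters each sensor with a five-point moving average
    with propagated uncertainty, normalizes by a per-session initialization
    reference, and flags left/right asymmetry when the uncertainty intervals of
    the top or bottom sensor pairs fail to overlap. Includes a session state
    machine with notification hooks, a consent-gated local event store with
    sitting-behavior summaries, and a seeded seat simulator that generates
    serial frames for scripted posture scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
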