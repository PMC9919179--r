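Package: icumotion
Title: Dual-Accelerometer Activity Classification for Intensive Care Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies the type, frequency, and duration of activities common
    to intensive-care patients (lying postures, semi-sitting, sitting,
    standing, walking, bed cycling, and transitions) from one chest-worn and
    one contralateral thigh-worn tri-axial accelerometer. Raw 20 Hz signals
    are median-filtered, split into a gravitational tilt component (0.25 Hz
    zero-phase low-pass) and body acceleration, converted to baseline-corrected
    body-segment angles and signal magnitude area (SMA), and classified at
    5 Hz epochs by a rule-based decision flowchart with a rest-activity SMA
    threshold. Includes a seeded synthetic dual-sensor recording simulator
    emulating scripted ICU activity protocols (natural, strict,
    healthcare-provider-assisted, bed cycling), and validation machinery:
    stream alignment by the first movement peak, 5 Hz resampling of
    annotations, per-class percentage agreement, confusion matrices, and
    ICC(A,1) with F-based confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
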