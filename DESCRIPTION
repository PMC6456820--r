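Package: oxyramp
Title: Ramp-Test Muscle Oxygenation and Cardiorespiratory Analysis with
    Work-Matched Eccentric Interval Prescription
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for incremental cycling ramp tests in
    cardiovascular rehabilitation. Extracts muscle oxygen saturation (SmO2)
    landmarks from near-infrared spectroscopy traces (zero-phase Butterworth
    filtering, deoxygenation minimum, half-reoxygenation kinetics),
    cardiorespiratory peak parameters (30-s peak oxygen uptake, 5-s peak
    heart rate, peak aerobic power, discrete blood-lactate and blood-pressure
    peaks), computes work-matched concentric/eccentric pedaling-type
    interval-training prescriptions, aggregates leg-press power-test
    attempts, and reports PRE/POST percentage changes. Includes a synthetic
    ramp-test generator with analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
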