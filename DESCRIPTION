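Package: SICDscreen
Title: Prolonged Subcutaneous ICD Eligibility Screening from Holter ECG
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prolonged (24-hour) eligibility screening for the
    subcutaneous implantable cardioverter-defibrillator (S-ICD) from
    three-channel Holter ECG. Provides a synthetic Holter generator with
    controllable ground-truth T:R amplitude ratios, an ASCII sample-table
    reader/writer, an ECG conditioning chain (baseline drift correction,
    50 Hz band-stop, 40 Hz low-pass), phase-space-reconstruction (PSR)
    delay-map imaging of 10-second segments, two per-segment T:R ratio
    estimators (a waveform peak-ratio estimator and a trainable PSR-image
    regressor evaluated by tenfold cross-validation), vector- and
    patient-level screening decisions at multiple T:R thresholds with a
    20-second consecutive-failure rule, and cohort-level statistics
    including an exact r x c Fisher test computed by complete enumeration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
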