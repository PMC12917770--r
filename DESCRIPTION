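Package: nirsprune
Title: Channel Pruning and Quality Control for Infant fNIRS Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quality assessment and channel pruning for two-wavelength
    functional near-infrared spectroscopy (fNIRS) recordings, oriented at
    infant data. Implements the coefficient-of-variation wavelength-difference
    rule, windowed scalp coupling index (SCI) and peak spectral power (PSP)
    pruning in the infant cardiac band, amplitude/deviation motion-artifact
    detection on optical-density changes, a retention-matched parameter sweep
    over SCI and PSP thresholds, and a bootstrap linear mixed-model stage that
    relates pruning parameters, age, and motion to signal quality and channel
    retention. Includes a synthetic infant-fNIRS cohort generator with ground
    truth so the full pipeline is testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
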