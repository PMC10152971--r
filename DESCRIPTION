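Package: vempnorm
Title: Pediatric Cervical VEMP Normative Values and Age-Specific Reference Intervals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for establishing and applying normative values for cervical
    vestibular evoked myogenic potentials (c-VEMP) in children, for both air-
    and bone-conducted 750 Hz tone bursts. Provides stimulus level calibration
    across the dB HL / nHL / FL / SPL scales, a synthetic cohort and waveform
    generator with the statistical structure of a pediatric normative study,
    waveform feature extraction (P and N peak latencies, peak-to-peak amplitude,
    tonic EMG level and the PN/EMG amplitude ratio), 5-dB staircase threshold
    determination with replicability checking, age- and sex-specific reference
    intervals for the amplitude ratio by the Royston-Wright method (Box-Cox
    transform with fractional-polynomial mean and SD curves), interaural
    asymmetry statistics, intraclass correlation for ear agreement, and
    classification of new measurements against the normative criteria.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
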