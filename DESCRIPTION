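Package: voicemarkers
Title: Acoustic Markers of Voice Identity and Owner-Voice Discrimination in Dogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end workflow for studying which acoustic cues support
    dogs' discrimination of their owner's voice in a two-way choice task.
    Provides a seeded source-filter voice synthesizer with analytically
    known ground truth, extraction of a 25-parameter acoustic feature
    battery (fundamental-frequency statistics, jitter, harmonics-to-noise
    ratio, Wiener entropy, spectral moments, formant dispersion), linear
    discriminant analysis of speaker identity with loading-based selection
    of identity markers, per-trial acoustic-distance covariates, simulation
    of the choice experiment under pseudorandomization constraints, and the
    binomial and Gaussian mixed-model analyses of choosing success and
    looking time, including backwards elimination and simple-slope post
    hoc tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
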