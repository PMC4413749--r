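Package: pamscape
Title: Calibrated Sound Level Analysis for Passive Acoustic Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts raw audio recordings from terrestrial or aquatic passive
    acoustic monitoring (PAM) systems into calibrated, absolute sound-pressure
    measurements and computes standard acoustic-habitat metrics: broadband
    sound pressure level (SPL), Welch power spectral density (PSD)
    spectrograms, one-third-octave band levels (TOL), sound exposure level
    (SEL), spectral probability density (SPD), percentile and exceedance
    statistics, and waveform-domain impulse metrics (peak levels, pulse SEL,
    90 percent energy envelope). Includes a synthetic-signal generator and a
    recorder-chain simulator (sensitivity, gain, quantization, clipping,
    self-noise) so every analysis is testable against known ground truth
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
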