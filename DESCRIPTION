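Package: eegretest
Title: Test-Retest Reliability of Resting-State EEG Spectral Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for quantifying the test-retest
    reliability of resting-state EEG power-spectral features. Simulates
    repeated-session multichannel EEG with a controlled variance-component
    structure (so the true intraclass correlation of every feature is
    known), applies a deterministic preprocessing chain (zero-phase FIR
    filtering, line-noise bandstop with harmonics, 2 s epoching,
    artifact-epoch rejection, spherical-spline interpolation of bad
    channels), extracts relative band power in five canonical bands and
    the individual alpha peak frequency via Welch's method, estimates
    ICC(A,1) with McGraw-Wong 95% confidence intervals per inter-session
    interval, and provides exact F-test power and sample-size planning
    for ICC study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
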