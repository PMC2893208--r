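Package: sleepbouts
Title: Sleep Stage Bout-Duration Dynamics: Multi-Exponential Fitting and
    Model Selection for Hypnograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing sleep-stage transition dynamics from
    epoch-coded hypnograms. Extracts stage bouts (WASO, NREM, REM) by
    run-length encoding, pools bout durations across subjects, builds
    one-epoch-binned relative-frequency histograms normalised to their
    maximal bin, and fits sums of 1-4 exponential decays by bounded
    nonlinear least squares with sequential nested model selection
    (extra sum-of-squares F-test and AICc). Includes power-law fitting
    and non-nested comparison, three normality tests for duration
    samples, a semi-Markov hypnogram simulator with stage-specific
    exponential-mixture dwell times, and simulation experiments on
    under-sampling and on multi-exponential mimicry of power laws.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    nortest,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
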