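Package: attnet
Title: Attention and Default Mode Network Analysis of Task and
    Resting-State fMRI Parcel Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Generates multiple-object-tracking and spatial-cueing oddball
    task designs, simulates parcel-level BOLD time series with programmable
    network correlation structure, fits condition GLMs with a gamma
    haemodynamic response function and computes region-of-interest percent
    signal change with sign-permutation cluster correction, implements a
    resting-state functional-connectivity pipeline (confound regression,
    framewise-displacement censoring with linear interpolation, band-pass
    filtering, run harmonization and per-hemisphere network correlation),
    and compares groups with pooled-variance t tests, Cohen's d and
    mixed-effects ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    lmerTest,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
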