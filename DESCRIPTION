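Package: electosleep
Title: Network-Based Sleep-Wake State Classification from Multi-Region LFP
    Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for EMG-free sleep-wake staging of multi-site rodent local
    field potential (LFP) recordings. Extracts per-window Welch cross-power
    spectral density features (within-region power and between-region
    synchrony), fits a supervised autoencoder whose non-negative decoder rows
    form interpretable "electome" factors, smooths predicted hypnograms with a
    top-k Viterbi decoder, computes sleep-architecture (bout) statistics, and
    compares feature tensors across experimental groups with per-feature
    t-tests combined into corrected harmonic-mean headline p-values. Includes
    a synthetic-cohort generator producing ground-truth-labeled recordings
    with state-dependent spectral content, cross-region shared components,
    EMG tone, and artifacts, plus an EMG-informed state-map labeler that
    replaces interactive cluster annotation with polygon configurations and
    an automatic initializer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
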