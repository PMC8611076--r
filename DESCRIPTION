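Package: lfpnet
Title: Burst Detection, Spectral Coherence and Directed Connectivity for
    Developmental Multi-Site LFP Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-site local field potential (LFP) and
    unit recordings from developing limbic circuits. Detects discontinuous
    oscillatory events (spindle bursts) with a variance-dependent threshold,
    computes Welch power spectra with baseline normalization, magnitude and
    imaginary coherence with shuffled-epoch nulls, fits multivariate
    autoregressive models and derives generalized partial directed coherence
    (gPDC), quantifies optogenetically evoked spiking (firing probability,
    PSTH, modulation index), evoked field responses and laminar current
    source density, extracts evoked EPSC features, and scores recognition
    behavior. A synthetic-data generator with known directed coupling, burst
    structure and laminar geometry provides ground truth for end-to-end
    recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    rhdf5,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
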