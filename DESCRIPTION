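Package: duetIBS
Title: Inter-Brain Synchrony from Amplitude-Envelope Phase Locking in
    Dual-EEG Duet Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies inter-brain synchrony (IBS) between two concurrently
    recorded EEG data sets from jointly performing musicians. Implements
    amplitude-envelope phase-locking values (PLV) between homologous
    electrodes over a sliding window grid, pointwise repeated-measures
    ANOVA with cluster-based permutation correction, baseline (within-dyad
    trial re-pairing) and surrogate-pair control analyses, duet keystroke
    timing metrics (signed and normalized asynchronies, lag-0 adaptation,
    entry asynchrony, inter-keystroke-interval matching), and mixed-effects
    brain-behavior models. A synthetic dyad generator with known
    ground-truth envelope coupling and timing effects makes the whole
    pipeline testable end to end without access to restricted recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
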