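Package: sleepmem
Title: Sleep EEG Event Detection and Emotional Memory Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying sleep-dependent emotional
    memory consolidation in within-subject, cross-over pharmacology designs.
    Provides synthetic generators for staged sleep EEG with ground-truth
    embedded sleep spindles and slow oscillations and for recognition-memory
    cohorts with known signal-detection parameters; EDF and hypnogram input
    and output with contralateral-mastoid re-referencing, zero-phase
    filtering, amplitude-threshold artifact rejection, and sleep-architecture
    metrics; Welch band power per sleep stage (slow-wave activity, delta,
    theta, slow and fast sigma); wavelet-threshold spindle detection,
    zero-crossing slow-oscillation detection, and slow-oscillation/spindle
    coupling density; confidence-rating memory scoring with d-prime; and the
    inferential layer (repeated-measures ANOVA with a weight covariate,
    paired t-tests, Holm-Bonferroni correction, and Bonferroni-screened
    Pearson correlations between sleep features and memory).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
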