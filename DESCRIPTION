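Package: spikeroc
Title: ROC-Based Analysis of Premovement Activity in Trial-Aligned Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for extracellular spike trains recorded from the
    rodent superior colliculus during a two-alternative audiovisual spatial
    discrimination task. Provides a synthetic-session generator (behavior,
    inhomogeneous-Poisson spike trains, tetrode wideband traces) with known
    ground truth; RMS-power spike detection and cluster quality metrics;
    Gaussian-kernel spike density functions and epoch firing rates; scaled ROC
    direction-preference and premovement-activity indices with permutation
    significance and sliding-window time courses; detection and classification
    of stimulus-evoked responses; reaction-time/firing-rate correlation typing
    of neurons into four movement-related classes; a multisensory modulation
    index; and the accompanying behavioral statistics (repeated-measures ANOVA
    with Tukey contrasts, paired muscimol-session comparisons, per-animal
    multisensory facilitation tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
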