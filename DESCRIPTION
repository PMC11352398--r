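Package: serpBCI
Title: Selective Tactile Attention Classification from Somatosensory ERPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for an electrotactile brain-computer
    interface (BCI) that classifies selective spatial tactile attention from
    single-channel somatosensory event-related potentials (sERPs). The package
    simulates the two-phase clinical protocol (classifier training blocks
    followed by online feedback trials) on synthetic multi-channel EEG,
    implements causal Butterworth filtering, epoching, baseline correction and
    amplitude-threshold artifact rejection, per-time-index Wilcoxon rank-sum
    feature screening, per-channel RBF support vector machines with
    leave-one-out channel selection, an online trial loop with a clean-epoch
    quota, and session/cohort reporting including Wolpaw information transfer
    rate, grand-average waveforms and subset comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
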