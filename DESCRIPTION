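Package: msinet
Title: Rate-Based and Spiking Network Model of Audio-Visual Integration in the Superior Colliculus
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates a population model of multisensory neurons in the deep
    superior colliculus. Eight coupled neuron populations with conductance-based
    rate dynamics combine auditory and visual Gaussian input fields under divisive
    pool normalization, feedforward coincidence inhibition and a cortical feedback
    circuit that gates multisensory enhancement. Includes the standard experiment
    suite for such models (inverse effectiveness, spatial principle,
    within-modality interactions, feedback ablation, near-optimal Bayesian cue
    fusion), a spike-rate backend that emulates the decomposition of the dynamics
    into elementary neuron operations with stochastic AND multiplication, and a
    command-line interface for running experiment sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
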