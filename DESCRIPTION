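Package: spikelapse
Title: Interictal Spike Dynamics During Spatial Working Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for interictal spikes (IS) recorded from hippocampal
    local field potentials while animals perform a delayed spatial-alternation task.
    Provides a tunable prominence-based IS detector with F-beta scoring against
    hand-labeled windows, an event taxonomy (solitary spikes, brief rhythmic
    interictal discharges, seizures), maze-zone segmentation and trial parsing,
    Skaggs spatial information of IS activity, hierarchical Bayesian Poisson models
    of zone- and behavioral-state-specific IS rate gains with MCMC and highest
    posterior density intervals, a sticky Bernoulli-emission hidden Markov model of
    trial-to-trial task engagement, IS waveform embedding and reward-zone decoding,
    and a CA3-CA1 spiking-network model (adaptive exponential integrate-and-fire
    neurons trained with spike-timing-dependent plasticity) of replay and its
    contamination by interictal input. A synthetic-data module generates every
    input the pipeline consumes so all stages run without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    randomForest,
    pROC,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
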