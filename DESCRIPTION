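Package: spikewm
Title: Embodied Working-Memory Simulation with Adaptive Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Desk-scale simulator of an embodied working-memory circuit: an
    adaptive exponential integrate-and-fire (aEIF) network of 500 units with
    Tsodyks-Markram short-term plasticity, nearest-neighbour multiplicative
    spike-timing-dependent plasticity (STDP), and structural plasticity, driven
    by bimodal Gaussian sensory currents and a frozen Poisson background.
    Population spike counts are decoded in 40 ms bins into differential-drive
    wheel speeds for a virtual two-wheeled agent. Ships six working-memory
    protocols (single and incremental learning/recall, task switching,
    interference resistance and submission, distraction resistance) with
    machine-evaluated success criteria, plus a command-line runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
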