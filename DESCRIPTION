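Package: izhinet
Title: Izhikevich Spiking Networks Under Neurodegeneration and Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and simulates cortical microcircuit models of Izhikevich
    integrate-and-fire neurons placed on a unit sphere, with delayed
    exponential-decay synapses, input desensitization, stochastic background
    drive, and additive spike-timing-dependent plasticity at
    excitatory-excitatory synapses. Implements progressive neurodegeneration
    protocols (random, focal, and firing-rate-targeted deletion),
    plasticity-mediated recovery, population oscillation detection from
    sliding-window spike counts, and the associated activity metrics and
    statistical comparisons.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Rcpp, stats, utils, graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
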