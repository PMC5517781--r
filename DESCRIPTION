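Package: spikenet
Title: Fixed-Step Spiking Neural Network Simulation and Benchmark Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained simulator for point-neuron spiking networks on a
    fixed time grid, built around two reference benchmark models: a 5,000-neuron
    leaky integrate-and-fire network with delta synapses that generates
    pyramidal-interneuron gamma (PING) oscillations, and a 400-neuron
    Hodgkin-Huxley network with double-exponential inhibitory synapses that
    generates gamma oscillations through post-inhibitory rebound (PIR-ING).
    Provides exact exponential propagation for linear membranes and synapse
    traces, exponential-Euler and classical Runge-Kutta solvers for
    conductance-based neurons, rate-function lookup tables with linear
    interpolation, seeded Bernoulli and fixed-out-degree connectivity builders
    with plain-text serialization, a ring-buffer event queue for delayed spike
    delivery, Poisson spike generators, spike-train summary statistics, and a
    comment-stripping source-code size metric (lines and characters of code).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
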