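Package: perturbNet
Title: Signed Signalling Network Inference from Perturbation Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reconstruction of directed signalling networks with activation
    and inhibition edges from longitudinal high-throughput measurements
    taken after external perturbation of network components. Network
    dynamics follow a dynamic deterministic effects propagation (Boolean)
    model; measurements are linked to propagated active/passive system
    states through per-protein two-component Gaussian emissions estimated
    by Viterbi training. Structure search is performed either by a
    Metropolis-Hastings MCMC sampler with six signed-edge move types or by
    a genetic algorithm, optionally guided by a Laplace prior that
    penalises deviations from a signed reference network or by a
    scale-free degree prior. Includes simulation of ground-truth networks
    and data, ROC/AUC edge-recovery evaluation, consensus-network
    construction and MCMC convergence diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cli.R'
    'evaluate.R'
    'ga.R'
    'mcmc.R'
    'network-io.R'
    'priors.R'
    'propagate.R'
    'simulate.R'
    'utils.R'
    'viterbi.R'
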