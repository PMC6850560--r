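Package: neuroassembly
Title: Bayesian Inference of Neuronal Assemblies from Binary Population Activity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects neuronal assemblies in binary population activity rasters
    with a hierarchical Bernoulli generative model. Neurons are grouped by a
    collapsed Gibbs sampler at fixed assembly number, or by a Dirichlet-process
    Metropolis-Hastings sampler that infers the number of assemblies from the
    data, yielding posterior estimates of assembly membership, on/off dynamics,
    activity, synchrony and asynchrony. Includes a hidden-Markov-model
    binarizer that extracts calcium-transient onsets (or firing-rate
    transients) from raw traces, frame- and assembly-selection filters,
    synthetic benchmark generators with a pairwise co-assignment performance
    metric, detectability phase-diagram drivers, and posterior analyses of
    assembly correlation graphs and spatial compactness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    igraph,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
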