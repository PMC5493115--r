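Package: olfmap
Title: Olfactory Population Coding Analysis from Spike Trains to Higher Brain Center Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of insect olfactory coding: conversion of
    spike trains from identified projection-neuron and sensory-neuron classes
    into control-subtracted odor-response matrices; tuning-curve and lifetime
    sparseness statistics of the sensory-to-projection-neuron transformation;
    odor-space geometry (cosine, Euclidean and correlation distances, Ward
    hierarchical clustering with fixed cuts, cluster-signature glomeruli, PCA,
    ANOSIM, matrix-matrix correlations with shuffle controls); voxel density
    maps from SWC neuron skeletons with boxcar smoothing; response-weighted
    virtual activity maps in the mushroom-body calyx and lateral horn; and
    time-resolved population trajectory analyses. Includes a synthetic-data
    generator (cluster-structured glomerular tuning, sister-neuron trial
    noise, inhomogeneous Poisson spike trains, random-walk axonal arbors) so
    the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
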