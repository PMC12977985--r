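Package: avmnet
Title: Connectome Analysis of Cognitive Impairment in Brain Arteriovenous
    Malformations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Lesion-aware brain network analysis for studying cognitive
    impairment as a network disconnection syndrome. Builds structural and
    functional connectomes from parcel-level matrices (Pearson functional
    connectivity, inverse-node-volume normalised streamline counts, lesion
    masking, proportional thresholding), computes weighted graph topology
    (global efficiency, Onnela clustering, strength ranks, virtual-lesion
    resilience with a random-attack null), per-node structure-function
    coupling, and fits a Network Diffusion Model (heat kernel on the
    normalised graph Laplacian) with a full epicenter seed sweep against an
    empirical atrophy map. Includes lesion burden and cognitive-domain
    scoring, robust brain-behaviour regression (OLS and Huber M-estimation),
    Benjamini-Hochberg corrected edgewise comparisons, a parameter
    sensitivity sweep, and a seeded synthetic cohort generator so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    MASS,
    igraph,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    optparse
Config/testthat/edition: 3
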