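Package: TopoCellSort
Title: Topological Classification of Multicellular Patterns from Differential
    Adhesion Simulations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based simulation of two (or more) motile, adhesive cell
    types with tunable homotypic and heterotypic adhesion and optional
    contact-inhibited proliferation, together with a topological
    data-analysis pipeline for unsupervised classification of the emergent
    multicellular patterns. Cell configurations are summarized by
    Vietoris-Rips persistence diagrams per cell-type channel, vectorized as
    dimension-0 and dimension-1 persistence images or persistence curves
    (with classical radial and angular order parameters as a baseline),
    embedded to a low-dimensional latent space (PCA, UMAP, diffusion
    potential, or a built-in autoencoder), and clustered with Ward linkage
    against an adhesion-regime phase taxonomy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    e1071
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    uwot,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
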