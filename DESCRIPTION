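Package: metaplexr
Title: Diffusion on Simplicial Complexes Modeled as Metaplexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds geometric simplicial complexes from graphs (clique
    complexes), assembles their signed incidence matrices, Hodge Laplacians
    and Betti numbers, and simulates two contrasting diffusion models on
    them: the higher-order (Hodge) Laplacian block dynamics, and the
    simplicial-metaplex model in which every simplex is a continuous domain
    discretized by piecewise-linear finite elements and coupled to its
    faces and cofaces through boundary sink-source conductances. Includes
    mass-conserving, positivity-preserving implicit integrators,
    per-simplex observables, return probabilities, topological hole
    detection from near-empty triangles, and side-by-side model
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    tibble,
    tidyr,
    generics,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
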