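Package: cmlearn
Title: Cognitive Map Learning for Online Planning and Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Implements a cognitive map learner: a neural model that builds a
    high-dimensional map of a problem space purely by local, self-supervised
    next-observation prediction (delta-rule plasticity), and then plans online
    by selecting, at each step, the afforded action whose embedding points most
    toward the goal. Includes generators for abstract graph worlds (random
    degree-constrained, small-world, dead-end, multi-path, edge-weighted),
    rectilinear and hexagonal 2D grid mazes with partial exploration, a
    point-mass continuous-control environment, a Dijkstra baseline,
    representational-geometry diagnostics (action-embedding cosine structure,
    cycle closure, distance scaling, parallelism score, PCA map projection),
    weight quantization, and reproducible experiment presets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
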