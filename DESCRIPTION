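Package: mfmicd
Title: Memetic Immunogenetic Community Detection for Functional Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Divides undirected networks into communities with a memetic
    immunogenetic algorithm: a modularity-driven genetic global search with
    identifier-passing initialisation, calibrated fitness, strongest-first
    circular crossover, dynamically adjusted crossover/mutation rates,
    roulette-wheel selection and a vaccination-style immune operator,
    refined by a penalised tabu local search. Includes the
    electroencephalography (EEG) pipeline the method was designed for:
    zero-phase theta-band filtering, analytic-signal phase extraction,
    phase-locking-value (PLV) connectivity, adaptive edge-count
    binarisation, and mapping of detected modules onto the 32-channel
    10-20 electrode layout with per-region node proportions. Ships
    partition-quality metrics (modularity, normalised mutual information),
    exhaustive-search oracles for testing, and seed-deterministic synthetic
    generators (planted-partition graphs, coupled-phase surrogate EEG,
    Zachary karate-club fixture).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    igraph,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
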