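Package: chemotaxdist
Title: Taxonomic Structure of Natural-Product Chemical Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tests whether taxonomically closer species produce chemically
    closer natural products. Molecules are embedded in a Euclidean chemical
    space (a deterministic hashed n-gram encoder is built in; externally
    computed embedding matrices are loadable), an asymmetric percentile-based
    interspecies chemical distance is computed from nearest-neighbour
    molecule-to-species distances, species pairs are stratified by integer
    taxonomic distance, and one-tailed Welch tests with Welch-Satterthwaite
    effective degrees of freedom are applied at pooled and per-reference-species
    levels, with hyperparameter sweeps. A synthetic generator simulates
    rank-level Brownian trait drift on a balanced taxonomy, plus confounders
    (ubiquitous metabolites, missing data, horizontal-transfer-like copying),
    so every stage is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ChemmineOB,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
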