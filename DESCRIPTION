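Package: kldnma
Title: Local Inconsistency in Network Meta-Analysis via Node-Splitting and
    Kullback-Leibler Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates local inconsistency in network meta-analysis of binary
    outcomes. Fits the Bayesian random-effects node-splitting model on the log
    odds-ratio scale for every comparison with independent direct and indirect
    evidence, and interprets the divergence between the two evidence sources
    with an index based on the average Kullback-Leibler divergence between
    their normal approximations, together with a semi-objective threshold of
    acceptably low inconsistency (approximately 0.64). Includes study-level
    event-risk filtering and network eligibility checks, treatment-network
    geometry tools (connectivity, closed loops, split-node enumeration),
    four-way node and network classification rules, prevalence summaries, and
    a synthetic-network generator so the whole pipeline runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    optparse
Config/testthat/edition: 3
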