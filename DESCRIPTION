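Package: histcirc
Title: Bistability Screening of Two-Position Histone Modification Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic agent-based simulation and exhaustive screening of
    nucleosome-modification "circuits" built on a two-position histone code.
    Four half-nucleosome types (unmodified/modified at each of two histone
    positions) interconvert through eight reactions, each either noise-only
    or catalysed by an enzyme recruited by one nucleosome type; a circuit
    code assigns the recruiting type per reaction. The package simulates
    recruitment, noise and replication dynamics, scores trajectories for
    balanced heritable bistability (balance, switching frequency,
    intermediate dwell time), screens circuit-code spaces exhaustively,
    detects the cooperativity motifs that underlie bistability (standard
    two-step and pull-push pathways, with or without a destabilised
    intermediate), analyses deterministic mean-field fixed points, and
    builds the single-mutation evolutionary network of working circuits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    deSolve,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
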