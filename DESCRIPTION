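Package: herdgame
Title: Evolutionary Pairwise Games with Herding Costs on Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monte-Carlo simulation of evolutionary two-player games on
    structured populations (toroidal lattices, Barabasi-Albert scale-free
    networks, well-mixed crowds) in which players may carry a herding
    mentality: a psychological cost, proportional to the fraction of a
    player's crowd behaving differently, is subtracted from game payoffs.
    Implements the generalized S-T pairwise game (R = 1, P = 0), Fermi
    pairwise imitation with mutation under synchronous updating, and an
    asymmetric four-strategy co-evolutionary game in which the herding
    trait itself is heritable. Includes drivers for S-T phase sweeps and
    herding-weight sensitivity analyses with stationary-state summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
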