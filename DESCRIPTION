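Package: tieprof
Title: Tie-Strength and Neighbourhood-Topology Correlation Profiles for
    Weighted Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures the interplay between edge weight (tie strength) and
    local topology in weighted networks. Implements symmetric and asymmetric
    neighbourhood overlaps, strength- and membership-normalised asymmetric
    weights, a weight-shuffling null model that preserves topology, and
    binned log-log correlation profiles (R and Z scores) that separate
    weight-placement correlations from the structural correlations induced
    by the asymmetric definitions themselves. Includes readers for plain and
    konect-style edge lists, bipartite projection, synthetic network
    generators with a tunable planted weight-overlap coupling, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
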