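Package: quartetwalk
Title: Randomized Quartet Random-Walk Phylogeny Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Incremental phylogeny reconstruction by a randomized walk over a
    ternary search tree, driven by weighted quartet queries. Builds a
    neighbour-joining guide tree on a subset of taxa, indexes it with a
    balanced search-tree decomposition, and inserts the remaining taxa by an
    error-tolerant random walk that aggregates several four-point quartet
    queries per step with weighted-majority or winner-takes-all voting, a
    confidence threshold, biased quartet choice, and multiple insertion
    rounds. Includes distance estimators (log-corrected Jukes-Cantor for
    nucleotides, a BLOSUM62 score-based distance for proteins), a
    tree-collection quartet oracle for supertree construction, Robinson-Foulds
    and quartet quality measures, and a pure-birth/Jukes-Cantor simulator with
    exponential rate variation across sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
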