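Package: bpmedian
Title: Breakpoint Medians, Geodesic Patches and Accessibility for Unsigned Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the breakpoint (bp) pseudometric on unsigned linear
    unichromosomal genomes represented as permutations of gene labels.
    Implements the equivalence of a genome with its full reversal (the metric
    quotient space of genome classes), adjacency sets and the bp distance,
    geodesic-patch membership and the union set of geodesic patches between
    two genomes, exact brute-force and Hamiltonian-path median solvers for
    small gene numbers, accessibility closures of genome sets, constructions
    of pairwise maximally-distant genome sets and of the non-geodesic pair
    family, and Monte-Carlo experiments on the adjacency statistics and
    median values of uniformly random genomes. Results are returned as
    tibbles with broom-style tidy() and glance() methods and ggplot2
    autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
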