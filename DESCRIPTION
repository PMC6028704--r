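Package: metenum
Title: Exhaustive Enumeration of Branched and Cyclic Pathways in
    Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents genome-scale metabolic networks as directed bipartite
    metabolite-reaction graphs and exhaustively enumerates every branched and
    cyclic biosynthetic pathway of bounded size between a set of seed
    metabolites and target metabolites. A precursor-guided breadth-first
    search first computes the scope of the seed set (all producible
    metabolites, visited and stuck reactions, and shortest-step counts); a
    memoised dynamic programme over integer partitions then assembles visited
    reactions into all complete reaction sub-networks of each exact size up
    to a user cut-off. Multiple organisms can be joined through a shared
    extracellular compartment to study cross-feeding in microbial
    communities. Post-enumeration analytics include Jaccard pathway
    similarity spectra, most-different pathway pairs, and detection of
    metabolites exchanged between community members. Models are read from
    SBML Level 2/3 or a plain tabular reaction-list format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
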