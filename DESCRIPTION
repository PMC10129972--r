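Package: phylocover
Title: Labellable Phylogenetic Networks and Expanding Covers of Finite Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with rooted phylogenetic networks through their
    encoding as expanding covers of finite sets. Implements the deterministic
    internal-vertex labelling algorithm, extraction of the cover of sibling
    sets from a labellable network, validation of the expanding-cover
    conditions, reconstruction of a network from its cover, and the order
    condition that characterises non-degenerate networks. Also provides
    membership predicates for common network classes (tree-child,
    tree-sibling, orchard, tree-based, normal), the derived-network quotient
    that maps an arbitrary network onto the labellable class, and the
    normalisation of a network via the Hasse diagram of its visible vertices.
    Random generators for networks and covers support property-based testing.
    Networks are read and written as extended Newick strings or edge-list
    tables; covers as JSON or line-oriented text.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
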