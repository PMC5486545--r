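Package: morphorank
Title: Tensor-Rank and Presheaf Analysis of Morphological Character Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Algebraic and geometric tools for analysing dependencies
    between morphological characters across taxa. Character clusters are
    identified as independent feature combinations in minimal outer-product
    (tensor-rank) decompositions of carrier-by-feature matrices, computed
    exactly over the rationals and GF(2) or numerically via the singular
    value decomposition, with an error-bounded (epsilon) rank for measured
    data. Feature co-occurrence frequencies and their joint tensors support
    independence testing, and the normalized co-occurrence matrix preserves
    the rank of the character table. Taxa are also modelled geometrically as
    partial sections over a base of features with finite fibers of values:
    restriction and extension move between higher and more specific taxa,
    innovation operators enlarge fibers, add features or amalgamate two
    features into one, and fiberwise group actions partition sections into
    gestalt classes. Classification utilities distinguish cladistic
    (perfect-phylogeny compatible, maximal-rank) from functional (low-rank,
    cluster-structured) correlation patterns, with seeded generators for
    both. Includes CSV/TSV and NEXUS STANDARD readers, JSON and Newick
    writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
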