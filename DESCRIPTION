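Package: pypfam
Title: Sequence-Network Detection and Census of the Photoactive Yellow
    Protein Family
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Delineates a compact sensory-domain protein family (modelled
    on the photoactive yellow protein, PYP) inside a large homologous
    superfamily: all-vs-all affine-gap pairwise alignment with
    Karlin-Altschul E-values, Markov clustering of the filtered
    similarity network with an inflation sweep, reference-anchored
    calling of the chromophore-binding residues (Tyr42/Glu46/Cys69 and
    clade signatures), iterative profile hidden Markov model building
    with conservation-based gathering cutoffs, gene-neighborhood and
    operon analysis, a phyletic census with display and
    horizontal-transfer flags, and neighbor-joining trees with
    anchor-based clade assignment.  Includes a synthetic-data generator
    emulating the statistical structure of the real protein and genome
    inputs so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    igraph,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    phangorn,
    optparse
Config/testthat/edition: 3
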