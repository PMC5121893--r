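Package: tith
Title: Transcriptome-Based Intratumor Heterogeneity from Network Entropy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies intratumor heterogeneity from bulk RNA-seq
    expression profiles overlaid on a protein-interaction network.
    Implements the network Jensen-Shannon divergence (nJSD) between two
    expression states, built from per-gene neighbor-expression
    probability distributions under a mass-action assumption, and the
    transcriptome-based heterogeneity score tITH = NT/(NT+TA), the ratio
    of the nJSD distance from a normal reference to the tumor (NT) over
    that distance plus the distance from the tumor to the maximally
    ambiguous network state in which all genes are equally expressed
    (TA). Includes pathway-level scoring against GMT gene-set
    collections, readers for expression tables and protein-interaction
    edge lists, a synthetic cohort generator, in-silico clone-mixing
    and bulk-versus-single-cell experiments, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
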