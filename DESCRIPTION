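Package: iinet
Title: Construction and Analysis of Interface-Interaction Networks
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds interface-interaction networks (IINs) from curated
    protein-protein interaction (PPI) edge lists and per-protein
    interface-overlap matrices, and characterizes them with clustering
    coefficients, an exact census of connected four-node motifs,
    degree-preserving (Maslov-Sneppen) null ensembles, discrete power-law
    fits with Kolmogorov-Smirnov model selection and bootstrap
    goodness-of-fit, module-size distributions, hypergeometric enrichment,
    and interface knockout queries. Also extracts inter-chain binding
    interfaces from multi-chain structure files at a heavy-atom distance
    cutoff and tabulates interface residue/atom overlap between binding
    partners, and ships seeded generators for synthetic PPIs with
    ground-truth interface assignments and for toy multi-chain structures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'hurwitz.R'
    'overlap-matrix.R'
    'core-model.R'
    'netstats.R'
    'motifs.R'
    'nullmodels.R'
    'powerlaw.R'
    'pdb-interfaces.R'
    'synthetic.R'
    'toy-structures.R'
    'io.R'
    'cli.R'
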