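Package: confsel
Title: Conformer Ensemble Clustering and Curtin-Hammett Selectivity
Version: 1.0.0
Authors@R:
    person("confsel", "maintainers", email = "confsel@example.org",
           role = c("aut", "cre"))
Description: Tools for untangling transition-state conformer ensembles and
    computing reaction selectivity under Curtin-Hammett conditions. Reads
    multi-frame XYZ ensembles with optional free energies, perceives
    molecular bond graphs, computes symmetry-corrected heavy-atom RMSDs via
    graph isomorphism, torsion-angle and energy dissimilarities, and fuses
    them into a compound distance matrix. Conformers are clustered into
    interconvertible families by multidimensional scaling plus k-means with
    silhouette-based model selection, and the lowest-energy representative
    of each family is sampled. Selectivity between two product pathways is
    computed by Boltzmann weighting within clusters and Eyring rate-constant
    summation across clusters, exposing the classic repeated-conformer and
    interconversion error modes. Includes a planted-structure synthetic
    ensemble generator and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    cluster,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
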