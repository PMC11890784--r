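Package: dccnet
Title: Dynamic Community Network Analysis of Molecular Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Covariance-based dynamic network analysis for conformational
    ensembles of biomolecular complexes. Reads multi-model PDB ensembles,
    superposes frames, computes residue fluctuation profiles (RMSF,
    crystallographic-style B-factors) and dynamic cross-correlation
    matrices, builds persistence-filtered contact networks with edge
    weights -ln|c_ij|, partitions them into dynamic communities by
    Girvan-Newman edge-betweenness removal with modularity tracking, and
    summarizes inter-community communication by cumulative betweenness.
    Also provides structure-geometry measures used alongside such
    analyses (atom-pair distances, lysine reach scans, duplex kink
    angles, Shrake-Rupley solvent-accessible surface areas and buried
    interface fractions), a nudged-elastic-band minimum-energy-path
    optimizer over analytic potentials, and a generator of synthetic
    ensembles with planted correlation-block communities for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    mclust,
    stats,
    tools,
    utils,
    yaml
Suggests:
    bio3d,
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
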