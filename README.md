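# dccnet

Dynamic community network analysis of molecular conformational
ensembles in R.

Large biomolecular assemblies — repair complexes, polymerase
machineries, ubiquitin ligases — move as collections of semi-rigid
modules whose boundaries cut across subunit annotations. `dccnet`
recovers those modules from a conformer ensemble (e.g. snapshots from
molecular dynamics) by covariance-based network analysis, and bundles
the surrounding measurements such studies report: per-residue
flexibility profiles, persistent-contact classification, interface
burial, distance-reach scans, DNA kink angles, and minimum-energy-path
optimization by the nudged elastic band method.

## The method

Given an ensemble of F conformers over a fixed topology:

1. **Nodes** are polymer residues, represented by Cα (protein) or P
   (nucleic acid) atoms.
2. **Edges** connect residue pairs whose minimum heavy-atom distance
   stays within 4.5 Å for at least 75% of frames (sequence neighbours
   excluded).
3. **Weights** are `w_ij = −ln|c_ij|`, with `c_ij` the linear dynamic
   cross-correlation `⟨Δr_i·Δr_j⟩ / √(⟨|Δr_i|²⟩⟨|Δr_j|²⟩)` of node
   displacements after Kabsch superposition — correlated pairs are
   close in the graph metric.
4. **Communities** come from Girvan–Newman partitioning: iteratively
   remove the highest-betweenness edge, track Newman modularity
   `Q = Σ_k (e_kk − a_k²)` on the unweighted contact graph, and return
   the partition at the modularity maximum, with the full Q trace
   exposed. Inter-community communication is summarized by cumulative
   betweenness (`community_graph()`).

Per-residue flexibility converts to crystallographic-style B-factors
as `B = (8π²/3)·MSF` and can be written back into PDB files for
structure-viewer colouring.

A first-class synthetic-ensemble generator plants block-correlated
communities (equicorrelated Gaussian displacements over a compact
fcc bead layout with controlled inter-block bridges) so every stage of
the pipeline can be validated against known ground truth.

## Worked example

Generate a planted two-block ensemble (10 + 10 residues, within-block
correlation 0.8, between-block 0.1, 5000 frames), run the pipeline,
and compare against the planted labels:

```r
library(dccnet)

spec <- synthetic_spec(blocks = c(10, 10), intra_corr = 0.8,
                       inter_corr = 0.1, n_frames = 5000, seed = 7)
sim   <- sample_ensemble(spec)
nodes <- select_nodes(sim$ensemble$topology)
ens   <- superpose(sim$ensemble, nodes)

pers  <- contact_persistence(ens, nodes, cutoff = 4.5)
edges <- contact_edges(pers, threshold = 0.75)
net   <- build_network(edges, correlation_matrix(ens, nodes))
part  <- girvan_newman(net)
part
#> community_partition: 2 communities, Q = 0.4778 ( weighted betweenness removal )

partition_ari(part$membership,
              attr(sim$ensemble$topology, "block")[nodes$atom])
#> [1] 1

half_trajectory_convergence(ens, nodes)$ari
#> [1] 1
```

The partition found at the modularity maximum (Q = 0.4778) is exactly
the planted pair of blocks (adjusted Rand index 1 against ground
truth), and rerunning the analysis independently on each half of the
frames gives the same partition (half-trajectory ARI 1) — the standard
convergence diagnostic for this kind of analysis. The same run as a
single call, with all reports (community table, Q trace, GraphML/JSON
graphs, B-factor-coloured PDB, manifest with checksums):

```r
run_pipeline(list(spec = spec, output_dir = "out"))
```

Other entry points: `rmsf_bfactor()` / `write_bfactors()` for
flexibility mapping, `classify_persistent_contacts()` for hydrogen
bond / salt bridge vs hydrophobic persistent contacts,
`lysine_reach_scan()`, `duplex_kink_angle()`, `sasa()` and
`buried_fraction()` for interface geometry, and `make_band()` /
`optimize_band()` / `path_profile()` for NEB minimum-energy paths over
analytic potentials.

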