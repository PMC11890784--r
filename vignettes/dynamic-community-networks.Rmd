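---
title: "Dynamic community networks from molecular ensembles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic community networks from molecular ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dccnet)
```

## The model

Large biomolecular machines move as collections of semi-rigid modules
whose boundaries rarely coincide with domain or subunit annotations.
Covariance-based dynamic network analysis recovers those modules from a
conformational ensemble in four steps, all implemented here:

1. **Nodes.** One node per polymer residue, represented by its Cα atom
   (amino acids) or P atom (nucleotides). Residues lacking the
   representative atom (5'-terminal nucleotides, chain breaks) are
   skipped with a warning rather than guessed at.
2. **Edges.** Two non-adjacent residues are connected when their
   minimum heavy-atom distance stays within 4.5 Å for at least 75% of
   the frames. Both boundaries are read literally: persistence exactly
   at the threshold is *in* contact ("at least"), and same-chain
   sequence neighbours (|Δresno| ≤ 1) are excluded because their
   contact is a trivial consequence of bonding. Inter-chain pairs are
   never excluded.
3. **Weights.** Each edge carries `w_ij = -ln|c_ij|`, where `c_ij` is
   the linear dynamic cross-correlation of the two nodes'
   representative-atom displacements,
   `c_ij = <Δr_i·Δr_j> / sqrt(<|Δr_i|²><|Δr_j|²>)`. Strongly correlated
   pairs are thus "close" in the graph metric. `|c|` is floored at
   1e-6 (with a warning), capping weights near 13.8; a truly
   uncorrelated contact should be a long edge, not an infinite one.
4. **Communities.** Girvan–Newman partitioning: repeatedly remove the
   edge with the highest betweenness, recomputing betweenness after
   every removal, and record the connected components and their
   modularity `Q = Σ_k (e_kk − a_k²)` after each step. The partition
   returned is the one maximizing Q over the whole removal trace, and
   the full Q trace is exposed so the modularity plateau can be
   inspected directly.

Inter-community communication is summarized by the cumulative
betweenness of inter-community edges (`community_graph()`), giving the
coarse-grained "communication graph" commonly drawn for such analyses.

### Choices the literature leaves open

Two details of this pipeline are genuinely underdetermined in the
dynamic-network-analysis lineage, and both are recorded in every run
manifest:

* **Betweenness weighting.** Edge removal uses *weighted* shortest
  paths (w as length) by default, which is the natural reading of
  `-ln|c|` as an information distance; an unweighted mode is available
  (`weighted = FALSE`). Modularity, by contrast, is always computed on
  the *unweighted* contact graph, so the partition quality measures
  topology rather than the weighting convention.
* **The stopping rule.** "Continue until the modularity plateaus" is
  operationalized as the global maximum of Q over the complete
  dendrogram, with deterministic tie-breaking (earliest step; edge ties
  resolve to the lexicographically smallest node pair). This makes runs
  bit-reproducible.

The correlation estimator is the signed linear (dot-product) DCCM — the
quantity inside `|·|` must be a signed coefficient — not a
mutual-information generalization.

## The synthetic ensemble generator

Real microsecond trajectories of systems in the size class this method
targets are not practical to regenerate or to ship, so validation rests
on ensembles with *planted* structure. The generator emulates exactly
the statistical features the pipeline consumes:

* **Topology.** Each block of nodes is laid out as a compact
  face-centred-cubic cluster with nearest-neighbour spacing 4.0 Å
  (inside the contact cutoff; second neighbours at 5.66 Å are safely
  outside it). Consecutive blocks are joined by a configurable number
  of bridge node pairs placed 4.0 Å apart while every other
  inter-block pair is kept beyond 6 Å; these separations are verified
  programmatically at build time and an infeasible request errors
  rather than silently degrading. The fcc arrangement (rather than a
  simple-cubic grid) is deliberate: it gives interior nodes up to
  twelve contacts and bridge nodes two to four anchors, so the planted
  blocks are densely knit and a bridge node cannot be split from its
  own block by betweenness-based removal. Residue numbers within a
  block are assigned so that sequence neighbours are never spatial
  contacts; the sequence-adjacency exclusion therefore removes no
  planted edge (for blocks of fewer than about four nodes no such
  numbering exists and the layout order is kept).
* **Displacements.** Per Cartesian axis, node i of block b moves as
  `σ(√inter·G + √(intra−inter)·B_b + √(1−intra)·e_i)` with independent
  standard normal factors. This equicorrelated construction hits the
  target correlations exactly (intra within a block, inter across
  blocks, per-coordinate variance σ²) and is positive semi-definite by
  construction for `0 ≤ inter ≤ intra < 1`.
* **Defaults.** `intra_corr = 0.8`, `inter_corr = 0.1`,
  `fluct_sigma = 0.3 Å`, `n_frames = 5000`, one bridge per block pair
  — the operating conditions at which recovery is exercised. The
  fluctuation scale of the real systems is not published; 0.3 Å per
  coordinate is a conventional magnitude for a stable interface and
  keeps contact persistence high (≈0.9) across bridges without ever
  breaking intra-block contacts.

What the generator does **not** emulate: time correlation (frames are
i.i.d. draws, not a trajectory), anisotropic or collective rigid-body
motions, force-field realism, solvent, or side-chain packing. Passing
the planted-recovery tests therefore demonstrates that the statistical
and graph machinery is correct at realistic signal levels — not that
any particular biological system partitions one way or another.

One interaction deserves note: rigid-body superposition removes the
global translation mode, which *is* the inter-block correlation factor
of the generator. After superposition the apparent inter-block
correlation changes sign and magnitude, but the contact topology is
untouched and block recovery is unaffected; estimator-recovery checks
are therefore run on the raw (already co-framed) ensembles, while the
community pipeline runs with superposition on, as it must for real
trajectories.

## Fluctuation statistics

Frames are superposed by Kabsch least squares (no scaling) on the
representative atoms of a configurable fit set (all nodes by default);
with the mean-structure reference the fit is iterated twice. Fewer than
three non-collinear fit atoms leave the rotation underdetermined and
raise an error. Per-node mean-square fluctuations convert to
crystallographic-style B-factors as `B = (8π²/3)·MSF`, written back
into PDB B-factor columns (`%6.2f`, clamped to [0, 999.99] with a
warning) for structure-viewer colouring. A zero-variance node would
make the correlation undefined; its row and column are set to zero
(diagonal 1) with a warning.

## Persistent-contact classification

Beyond the binary contact map, residue pairs can be classified the way
persistent interactions are conventionally reported: a hydrogen-bond /
salt-bridge event when any inter-residue N/O–N/O pair is within 3.5 Å,
a hydrophobic event when any apolar carbon pair is within 4.5 Å, and a
contact is *persistent* when its event fraction exceeds 0.60 — a strict
inequality, read literally from the convention "more than 60% of
frames". Donor/acceptor chemistry is deliberately not perceived:
N/O proximity is the operational rule, and apolar carbons are
identified by the PDB remoteness-letter heuristic (a side-chain carbon
is polar when its residue carries an N/O at the next remoteness
letter; backbone C/CA are always polar). No angular criteria and no
π-stacking detection are attempted.

## Geometry measures

* `pair_distance()` — Euclidean distances per conformer with
  min/mean/max summaries.
* `lysine_reach_scan()` — every LYS on the target chains whose NZ atom
  (the chemically attacked amine; Cα fallback is flagged) comes
  *strictly* within the cutoff (default 12 Å) of a reference atom in
  any conformer; the union over conformers is reported with per-residue
  minimum distances. The strict boundary mirrors the "< 12 Å"
  convention for ubiquitination-competent geometry.
* `duplex_kink_angle()` — each arm's axis is the first principal
  direction of its backbone atoms, oriented away from the junction
  (away from the arm's atom nearest the other arm), so 180° is straight
  and the convention is unambiguous; a ~140° reading means a 40° bend.
  A curve-fit helical axis is out of scope; the principal-direction
  proxy is accurate to well under a degree on duplex-scale arms.
* `sasa()` — Shrake–Rupley with deterministic Fibonacci-spiral sphere
  points (default 960; the discretization error on two touching
  carbons is ≈0.1% against a 10⁵-point reference), probe 1.4 Å, radii
  C 1.70 / N 1.55 / O 1.52 / S 1.80 / P 1.80 / H 1.20 / other 1.70 Å,
  hydrogens included when present.
* `buried_fraction()` — (SASA alone − SASA in complex) / SASA alone,
  with a per-partner decomposition by removing one partner at a time
  and normalizing the restored areas.

## The elastic-band module

`optimize_band()` implements improved-tangent (uphill-neighbour) NEB
over pluggable analytic potentials, with a partial-band mask under
which tangent and spring act only on the masked coordinates while the
rest feel the bare potential force. The optimizer is deterministic
FIRE-style quenched descent rather than thermal Langevin dynamics:
on desk-scale analytic surfaces thermal sampling adds noise and no
information. Convergence is declared after ten consecutive iterations
whose maximum replica displacement falls below the tolerance (a single
tiny step is not trusted, because steps are transiently small while
the quenched velocity rebuilds), and non-convergence at the iteration
budget flags the result rather than raising. Endpoints are pinned
bit-identically. A climbing-image mode (off by default) lifts the
highest-energy replica along the tangent without spring forces; it is
the standard refinement when the saddle itself is the quantity of
interest — with 16 replicas on the Müller–Brown surface the plain band
brackets the saddle to ≈0.07 while the climbing image lands on it to
≈1e-4. The default spring constant of 10 (energy·length⁻²) is the
value conventional for molecular-scale coordinates in
kcal mol⁻¹ Å⁻²; benchmark-surface runs use k = 0.1 to match the much
smaller energy scale.

## Reproducibility and problem sizes

Every source of randomness flows from one explicit integer seed;
`sample_ensemble()` restores the caller's RNG state. `run_pipeline()`
writes a manifest recording every parameter, each methodological
decision flag, summary results and an MD5 checksum of every output
file; identical configurations reproduce identical checksums.

The validation suite exercises: planted recovery at 10+10 nodes ×
5000 frames over five seeds (and 8+8 nodes at the weaker
intra 0.7 / inter 0.2 signal over ten seeds), estimator recovery at
10⁴ frames, exhaustive max-modularity comparison on all fixture graphs
up to 8 nodes, and a 2000×2000 grid-search saddle oracle for the NEB
benchmark. These sizes were chosen to estimate each quantity to well
inside its asserted tolerance while keeping a full run in tens of
seconds.

## Known limitations

* Frames are treated as exchangeable; no statistical correction for
  time correlation is made (the half-trajectory convergence report is
  the provided diagnostic).
* Modularity's resolution limit is inherited: very small or very
  weakly separated modules can merge or split at the global-max-Q cut.
  The exported Q trace and dendrogram allow any other cut to be taken.
* The contact rule uses heavy atoms only and no angular terms.
* Ensembles are held in memory (F × A × 3 doubles); microsecond
  all-atom trajectories should be node-reduced or subsampled upstream.
* The NEB module targets analytic benchmark surfaces; it demonstrates
  the algorithmic core (tangent projection, springs, partial masks,
  climbing image), not an interface to molecular force fields.
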