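# Shared fixtures and independent oracles, all built in code.

# One atom record row for hand-built structure models.
atom_row <- function(name, el, x, y, z, chain = "A", resno = 1L,
                     resname = "ALA", het = FALSE, occ = 1, b = 0,
                     altloc = " ", icode = " ") {
  data.frame(record = if (het) "HETATM" else "ATOM", serial = 0L,
             name = name, altloc = altloc, resname = resname,
             chain = chain, resno = as.integer(resno), icode = icode,
             x = x, y = y, z = z, occ = occ, b = b, element = el,
             het = het, stringsAsFactors = FALSE)
}

fixture_model <- function(...) {
  atoms <- do.call(rbind, list(...))
  atoms$serial <- seq_len(nrow(atoms))
  dccnet:::new_structure_model(atoms)
}

# Ensemble from a list of coordinate matrices (frames) over a model.
fixture_ensemble <- function(model, frames) {
  xyz <- array(NA_real_, dim = c(length(frames), nrow(model$atoms), 3))
  for (f in seq_along(frames)) xyz[f, , ] <- frames[[f]]
  dccnet:::new_trajectory_ensemble(model, xyz)
}

model_coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

# A dynamic network with uniform weights from an explicit edge list
# (for pure graph-algorithm tests): all correlations 0.5, so weighted
# betweenness is proportional to unweighted.
uniform_network <- function(edge_list, n) {
  cmat <- matrix(0.5, n, n)
  diag(cmat) <- 1
  class(cmat) <- c("correlation_matrix", class(cmat))
  edges <- data.frame(i = edge_list[, 1], j = edge_list[, 2], p = 1)
  build_network(edges, cmat)
}

# Fixture graphs for the community-detection oracle suite (<= 8 nodes).
fixture_graphs <- function() {
  list(
    two_triangles_bridge = list(
      n = 6, edges = rbind(c(1, 2), c(1, 3), c(2, 3), c(3, 4),
                           c(4, 5), c(4, 6), c(5, 6))),
    k4 = list(n = 4, edges = t(combn(4, 2))),
    path4 = list(n = 4, edges = rbind(c(1, 2), c(2, 3), c(3, 4))),
    two_squares_bridge = list(
      n = 8, edges = rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(4, 5),
                           c(5, 6), c(6, 7), c(7, 8), c(8, 5))),
    star5 = list(n = 5, edges = cbind(1, 2:5)),
    triangles_with_pendant = list(
      n = 7, edges = rbind(c(1, 2), c(1, 3), c(2, 3), c(3, 4),
                           c(4, 5), c(4, 6), c(5, 6), c(6, 7)))
  )
}

# Exhaustive enumeration of all set partitions of n elements
# (restricted-growth strings); the independent oracle for the
# max-modularity partition on small graphs.
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels, k) {
    if (length(labels) == n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (g in seq_len(k + 1)) grow(c(labels, g), max(k, g))
  }
  grow(integer(0), 0L)
  out
}

best_partition_exhaustive <- function(edges, n) {
  parts <- all_partitions(n)
  ed <- data.frame(i = edges[, 1], j = edges[, 2])
  qs <- vapply(parts, function(p) modularity_q(p, ed, n), numeric(1))
  list(q = max(qs), membership = parts[[which.max(qs)]])
}

# A lysine whose NZ sits `d` Angstrom from the origin along x.
lys_at <- function(d, chain = "L", resno = 1) {
  list(atom_row("CA", "C", d + 1.5, 0, 0, chain = chain, resno = resno,
                resname = "LYS"),
       atom_row("NZ", "N", d, 0, 0, chain = chain, resno = resno,
                resname = "LYS"))
}

# Planted two-block ensemble used across tests.
planted_sim <- function(seed, n_frames = 2000, blocks = c(10, 10),
                        intra = 0.8, inter = 0.1) {
  spec <- synthetic_spec(blocks, intra_corr = intra, inter_corr = inter,
                         n_frames = n_frames, seed = seed)
  sim <- sample_ensemble(spec)
  sim$nodes <- select_nodes(sim$ensemble$topology)
  sim$blocks <- attr(sim$ensemble$topology, "block")[sim$nodes$atom]
  sim
}

run_community_pipeline <- function(ensemble, nodes, threshold = 0.75,
                                   cutoff = 4.5) {
  p <- contact_persistence(ensemble, nodes, cutoff)
  ed <- contact_edges(p, threshold)
  cm <- correlation_matrix(ensemble, nodes)
  net <- build_network(ed, cm)
  girvan_newman(net)
}
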