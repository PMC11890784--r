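# Dynamic network construction, edge betweenness, Girvan-Newman
# partitioning, modularity and community-level summaries.

test_that("edge weights follow w = -ln|c| with a floored magnitude", {
  cmat <- rbind(c(1, 1, 0.5, 0), c(1, 1, 0.2, 0.1),
                c(0.5, 0.2, 1, -0.8), c(0, 0.1, -0.8, 1))
  class(cmat) <- c("correlation_matrix", class(cmat))
  edges <- data.frame(i = c(1, 1, 3), j = c(2, 3, 4), p = 1)
  net <- build_network(edges, cmat)
  expect_equal(net$edges$w, c(0, log(2), -log(0.8)), tolerance = 1e-12)
  # floored magnitude warns and caps the weight near 13.8155
  edges0 <- data.frame(i = 1, j = 4, p = 1)
  expect_warning(net0 <- build_network(edges0, cmat), "floor")
  expect_equal(net0$edges$w, -log(1e-6), tolerance = 1e-9)
  # out-of-range node index is an error
  expect_error(build_network(data.frame(i = 1, j = 9, p = 1), cmat),
               "missing")
})

test_that("edge betweenness matches hand enumeration", {
  fg <- fixture_graphs()
  # two triangles + bridge: all 9 cross pairs use the bridge
  net <- uniform_network(fg$two_triangles_bridge$edges, 6)
  eb <- edge_betweenness(net, weighted = FALSE)
  bridge <- which(net$edges$i == 3 & net$edges$j == 4)
  expect_equal(eb[bridge], 9)
  # 3-node path: both edges carry 2 pairs
  net2 <- uniform_network(rbind(c(1, 2), c(2, 3)), 3)
  expect_equal(edge_betweenness(net2, weighted = FALSE), c(2, 2))
  # symmetric square: all edges equal
  net3 <- uniform_network(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)), 4)
  expect_equal(diff(range(edge_betweenness(net3))), 0)
  # uniform weights scale lengths but not path structure
  expect_equal(edge_betweenness(net, weighted = TRUE),
               edge_betweenness(net, weighted = FALSE))
})

test_that("modularity follows the Newman formula", {
  fg <- fixture_graphs()
  ed <- data.frame(i = fg$two_triangles_bridge$edges[, 1],
                   j = fg$two_triangles_bridge$edges[, 2])
  # hand evaluation with m = 7: Q = 6/7 - 2 (1/2)^2 = 0.357142...
  expect_equal(modularity_q(c(1, 1, 1, 2, 2, 2), ed, 6), 5 / 14,
               tolerance = 1e-12)
  # single community -> 0; singleton partition of K4 is negative
  expect_equal(modularity_q(rep(1, 6), ed, 6), 0)
  k4 <- data.frame(i = t(combn(4, 2))[, 1], j = t(combn(4, 2))[, 2])
  expect_equal(modularity_q(1:4, k4, 4), -sum(rep(3 / 12, 4)^2),
               tolerance = 1e-12)
  expect_error(modularity_q(c(1, 1, NA, 2, 2, 2), ed, 6), "missing")
})

test_that("modularity agrees with igraph on arbitrary partitions", {
  fg <- fixture_graphs()
  for (g in fg) {
    ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
    ig <- igraph::add_vertices(ig, g$n - igraph::vcount(ig))
    set.seed(1)
    for (rep in 1:5) {
      memb <- sample(1:3, g$n, replace = TRUE)
      expect_equal(modularity_q(memb, data.frame(i = g$edges[, 1],
                                                 j = g$edges[, 2]), g$n),
                   igraph::modularity(ig, memb), tolerance = 1e-12)
    }
  }
})

test_that("Girvan-Newman recovers the two triangles and reports the trace", {
  fg <- fixture_graphs()
  net <- uniform_network(fg$two_triangles_bridge$edges, 6)
  part <- girvan_newman(net)
  expect_equal(part$n_communities, 2)
  expect_equal(part$membership, c(1, 1, 1, 2, 2, 2))
  expect_equal(part$q, 5 / 14, tolerance = 1e-12)
  # the bridge is removed first
  expect_equal(unlist(part$trace[2, c("removed_i", "removed_j")]),
               c(removed_i = 3, removed_j = 4))
  # Q returned always equals modularity recomputed from the labels
  expect_equal(part$q, modularity_q(part$membership, net), tolerance = 1e-12)
  for (s in seq_along(part$memberships)) {
    expect_equal(part$trace$q[s],
                 modularity_q(part$memberships[[s]], net),
                 tolerance = 1e-12)
  }
})

test_that("K4 returns the single community at step 0", {
  net <- uniform_network(t(combn(4, 2)), 4)
  part <- girvan_newman(net)
  expect_equal(part$n_communities, 1)
  expect_equal(part$q, 0)
  expect_equal(part$trace$step[which.max(part$trace$q)], 0)
})

test_that("identical inputs give identical partitions (tie rule)", {
  net <- uniform_network(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)), 4)
  a <- girvan_newman(net)
  b <- girvan_newman(net)
  expect_identical(a$membership, b$membership)
  expect_identical(a$trace, b$trace)
  # ties resolve toward the lexicographically smallest pair
  expect_equal(unlist(a$trace[2, c("removed_i", "removed_j")]),
               c(removed_i = 1, removed_j = 2))
})

test_that("an edgeless network warns and yields singleton communities", {
  cmat <- diag(3)
  class(cmat) <- c("correlation_matrix", class(cmat))
  net <- build_network(data.frame(i = integer(), j = integer(),
                                  p = double()), cmat)
  expect_warning(part <- girvan_newman(net), "edgeless")
  expect_equal(part$membership, 1:3)
  expect_equal(part$q, 0)
})

test_that("best-Q GN partition equals the exhaustive max-modularity one", {
  for (g in fixture_graphs()) {
    net <- uniform_network(g$edges, g$n)
    part <- suppressWarnings(girvan_newman(net))
    oracle <- best_partition_exhaustive(g$edges, g$n)
    expect_equal(part$q, oracle$q, tolerance = 1e-10)
    expect_equal(partition_ari(part$membership, oracle$membership), 1)
  }
})

test_that("the community graph aggregates inter-community betweenness", {
  fg <- fixture_graphs()
  net <- uniform_network(fg$two_triangles_bridge$edges, 6)
  part <- girvan_newman(net)
  cg <- community_graph(net, part, weighted = FALSE)
  expect_equal(cg$communities$size, c(3, 3))
  expect_equal(nrow(cg$edges), 1)
  expect_equal(cg$edges$weight, 9)
  # single community -> no edges
  cg1 <- community_graph(net, rep(1, 6))
  expect_equal(nrow(cg1$edges), 0)
  # three blocks in a chain -> a 3-node path
  sim <- planted_sim(31, n_frames = 400, blocks = c(8, 8, 8))
  part3 <- run_community_pipeline(sim$ensemble, sim$nodes)
  cg3 <- community_graph(
    build_network(contact_edges(contact_persistence(sim$ensemble,
                                                    sim$nodes)),
                  correlation_matrix(sim$ensemble, sim$nodes)),
    part3)
  expect_equal(nrow(cg3$communities), 3)
  expect_equal(nrow(cg3$edges), 2)
})

test_that("planted blocks are recovered across seeds", {
  for (seed in 1:5) {
    sim <- planted_sim(seed, n_frames = 2000)
    part <- run_community_pipeline(sim$ensemble, sim$nodes)
    expect_equal(partition_ari(part$membership, sim$blocks), 1)
  }
})

test_that("planted recovery holds across the stated parameter range", {
  # intra >= 0.7, inter <= 0.2, blocks >= 8: ARI >= 0.9 (10 seeds)
  aris <- vapply(1:10, function(seed) {
    sim <- planted_sim(seed, n_frames = 2000, blocks = c(8, 8),
                       intra = 0.7, inter = 0.2)
    part <- run_community_pipeline(sim$ensemble, sim$nodes)
    partition_ari(part$membership, sim$blocks)
  }, numeric(1))
  expect_true(all(aris >= 0.9))
})

test_that("half-trajectory convergence behaves at both extremes", {
  # identical halves -> ARI exactly 1
  sim <- planted_sim(41, n_frames = 200, blocks = c(6, 6))
  xyz <- sim$ensemble$xyz
  mirrored <- dccnet:::new_trajectory_ensemble(
    sim$ensemble$topology, xyz[c(1:100, 1:100), , ])
  h <- half_trajectory_convergence(mirrored, sim$nodes)
  expect_equal(h$ari, 1)
  expect_equal(h$q[1], h$q[2])
  # independent white-noise halves on an edgeless graph still report
  m <- fixture_model(atom_row("CA", "C", 0, 0, 0, resno = 1),
                     atom_row("CA", "C", 50, 0, 0, chain = "B", resno = 1))
  set.seed(5)
  frames <- lapply(1:8, function(f) {
    model_coords(m) + matrix(rnorm(6, sd = 0.1), ncol = 3)
  })
  h2 <- suppressWarnings(
    half_trajectory_convergence(fixture_ensemble(m, frames),
                                select_nodes(m)))
  expect_true(is.finite(h2$ari))
})

test_that("graph exports are readable", {
  net <- uniform_network(fixture_graphs()$two_triangles_bridge$edges, 6)
  part <- girvan_newman(net)
  gml <- tempfile(fileext = ".graphml")
  write_graph_file(net, gml, "graphml")
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(back), 7)
  js <- tempfile(fileext = ".json")
  write_graph_file(community_graph(net, part), js, "json")
  parsed <- jsonlite::read_json(js)
  expect_equal(length(parsed$nodes), 2)
})
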