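# Correlation-weighted contact networks, Girvan-Newman community
# detection with modularity tracking, and community-level summaries.
#
# Edge removal uses weighted shortest-path betweenness by default
# (w = -ln|c| as edge length, so strongly correlated pairs are "close");
# modularity is always evaluated on the original unweighted contact
# graph. Both choices are recorded in the partition object.

#' Build the correlation-weighted dynamic network
#'
#' One edge per contact pair, weighted `w = -ln(max(|c|, floor))`. A
#' correlation magnitude below the floor is floored with a warning
#' (capping `w` at about 13.82 for the default floor).
#'
#' @param edges Contact edge data frame from [contact_edges()]
#'   (columns `i`, `j`).
#' @param cmat A `correlation_matrix` over the same node set.
#' @param floor Correlation magnitude floor (default `1e-6`).
#' @return A `dynamic_network`: list with `n_nodes`, `edges` (data
#'   frame `i`, `j`, `c`, `w`) and `node_labels`.
#' @export
build_network <- function(edges, cmat, floor = 1e-6) {
  n <- nrow(cmat)
  if (nrow(edges) > 0 && (max(edges$i, edges$j) > n || min(edges$i, edges$j) < 1)) {
    stop_dccnet("contact pair refers to a node missing from the ",
                "correlation matrix")
  }
  cvals <- unclass(cmat)[cbind(edges$i, edges$j)]
  mag <- abs(cvals)
  if (any(mag < floor)) {
    warning(sum(mag < floor), " edge(s) with |c| below the floor ",
            format(floor), "; weight capped at ", round(-log(floor), 4),
            call. = FALSE)
    mag <- pmax(mag, floor)
  }
  ed <- data.frame(i = edges$i, j = edges$j, c = cvals, w = -log(mag))
  ed <- ed[order(ed$i, ed$j), , drop = FALSE]
  rownames(ed) <- NULL
  structure(list(n_nodes = n, edges = ed,
                 node_labels = rownames(cmat) %||% as.character(seq_len(n))),
            class = "dynamic_network")
}

#' Edge betweenness of a dynamic network
#'
#' All-pairs shortest-path betweenness with fractional splitting among
#' equal-length paths (Brandes accumulation); each unordered
#' source-target pair is counted once. In weighted mode the edge weight
#' `w` serves as the edge length.
#'
#' @param network A `dynamic_network`.
#' @param weighted Use `w` as edge length (default `TRUE`).
#' @return Numeric vector of betweenness values aligned with
#'   `network$edges`.
#' @export
edge_betweenness <- function(network, weighted = TRUE) {
  if (nrow(network$edges) == 0) return(numeric(0))
  if (weighted && any(network$edges$w < 0)) {
    stop_dccnet("negative edge weight")
  }
  g <- network_igraph(network)
  igraph::edge_betweenness(
    g, directed = FALSE,
    weights = if (weighted) igraph::E(g)$w else NA)
}

#' Girvan-Newman community detection with modularity tracking
#'
#' Iteratively removes the edge of highest betweenness (recomputed
#' after every removal; ties broken toward the lexicographically
#' smallest `(i, j)`), recording after each removal the connected
#' components and their modularity on the original unweighted contact
#' graph, until no edges remain. Returns the partition maximizing Q
#' (earliest step on ties) together with the full Q trace for plateau
#' inspection.
#'
#' @param network A `dynamic_network`.
#' @param weighted Use weighted betweenness for edge removal (default
#'   `TRUE`).
#' @return A `community_partition`: list with `membership` (integer
#'   labels, one per node), `q`, `n_communities`, `trace` (data frame
#'   `step`, `n_communities`, `q`, `removed_i`, `removed_j`),
#'   `memberships` (list of label vectors per step) and `weighted`.
#' @export
girvan_newman <- function(network, weighted = TRUE) {
  n <- network$n_nodes
  ed0 <- network$edges
  if (nrow(ed0) == 0) {
    warning("edgeless network: every node is its own community, Q = 0",
            call. = FALSE)
    membership <- seq_len(n)
    return(new_partition(membership, 0, data.frame(
      step = 0L, n_communities = n, q = 0,
      removed_i = NA_integer_, removed_j = NA_integer_),
      list(membership), weighted, network))
  }
  g <- network_igraph(network)
  memb <- igraph::components(g)$membership
  steps <- list(list(step = 0L, membership = as.integer(memb),
                     q = modularity_q(memb, ed0, n),
                     removed = c(NA_integer_, NA_integer_)))
  step <- 0L
  while (igraph::ecount(g) > 0) {
    eb <- igraph::edge_betweenness(
      g, directed = FALSE,
      weights = if (weighted) igraph::E(g)$w else NA)
    top <- which(eb >= max(eb) - 1e-10)
    if (length(top) > 1) {
      ends <- igraph::ends(g, igraph::E(g)[top], names = FALSE)
      ends <- t(apply(ends, 1, sort))
      top <- top[order(ends[, 1], ends[, 2])[1]]
    }
    removed <- sort(as.integer(igraph::ends(g, igraph::E(g)[top],
                                            names = FALSE)))
    g <- igraph::delete_edges(g, igraph::E(g)[top])
    memb <- as.integer(igraph::components(g)$membership)
    step <- step + 1L
    steps[[step + 1L]] <- list(step = step, membership = memb,
                               q = modularity_q(memb, ed0, n),
                               removed = removed)
  }
  qs <- vapply(steps, `[[`, numeric(1), "q")
  best <- which.max(qs)  # earliest max on ties
  trace <- data.frame(
    step = vapply(steps, `[[`, integer(1), "step"),
    n_communities = vapply(steps, function(s) length(unique(s$membership)),
                           integer(1)),
    q = qs,
    removed_i = vapply(steps, function(s) s$removed[1], integer(1)),
    removed_j = vapply(steps, function(s) s$removed[2], integer(1)))
  new_partition(relabel(steps[[best]]$membership), qs[best], trace,
                lapply(steps, `[[`, "membership"), weighted, network)
}

#' Newman modularity of a partition on an unweighted graph
#'
#' `Q = sum_k (e_kk - a_k^2)` with `e_kk` the fraction of edges inside
#' community `k` and `a_k` the fraction of edge endpoints in `k`.
#'
#' @param membership Integer community label per node.
#' @param edges Edge data frame (`i`, `j`) of the unweighted graph, or
#'   a `dynamic_network`.
#' @param n_nodes Number of nodes (inferred from a `dynamic_network`).
#' @return Modularity Q (0 by convention for an edgeless graph).
#' @export
modularity_q <- function(membership, edges, n_nodes = length(membership)) {
  if (inherits(edges, "dynamic_network")) {
    n_nodes <- edges$n_nodes
    edges <- edges$edges
  }
  if (anyNA(membership) || length(membership) < n_nodes) {
    stop_dccnet("membership label missing for some node")
  }
  m <- nrow(edges)
  if (m == 0) return(0)
  li <- membership[edges$i]
  lj <- membership[edges$j]
  labs <- unique(membership)
  e_kk <- vapply(labs, function(k) sum(li == k & lj == k), numeric(1)) / m
  ends <- c(li, lj)
  a_k <- vapply(labs, function(k) sum(ends == k), numeric(1)) / (2 * m)
  sum(e_kk - a_k^2)
}

#' Coarse-grained community graph
#'
#' One node per community (sized by member count); the weight of a
#' community-pair edge is the cumulative betweenness of the original
#' network's inter-community edges.
#'
#' @param network A `dynamic_network`.
#' @param partition A `community_partition` (or an integer membership
#'   vector).
#' @param weighted Use weighted betweenness (default `TRUE`).
#' @return A `community_graph`: list with `communities` (data frame
#'   `label`, `size`) and `edges` (data frame `a`, `b`, `weight`).
#' @export
community_graph <- function(network, partition, weighted = TRUE) {
  membership <- if (inherits(partition, "community_partition")) {
    partition$membership
  } else as.integer(partition)
  eb <- edge_betweenness(network, weighted = weighted)
  ed <- network$edges
  la <- membership[ed$i]
  lb <- membership[ed$j]
  inter <- la != lb
  labs <- sort(unique(membership))
  comm <- data.frame(label = labs,
                     size = vapply(labs, function(k) sum(membership == k),
                                   integer(1)))
  if (!any(inter)) {
    return(structure(list(communities = comm,
                          edges = data.frame(a = integer(), b = integer(),
                                             weight = double())),
                     class = "community_graph"))
  }
  a <- pmin(la[inter], lb[inter])
  b <- pmax(la[inter], lb[inter])
  agg <- stats::aggregate(list(weight = eb[inter]),
                          by = list(a = a, b = b), FUN = sum)
  agg <- agg[order(agg$a, agg$b), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(communities = comm, edges = agg),
            class = "community_graph")
}

#' First- versus second-half convergence of the community pipeline
#'
#' Runs the contact -> correlation -> network -> community pipeline
#' independently on the first and second half of the frames and
#' reports the adjusted Rand index between the two partitions together
#' with per-half modularity and community counts.
#'
#' @param ensemble A `trajectory_ensemble` with at least 4 frames.
#' @param nodes A `node_set`.
#' @param cutoff Contact cutoff in Angstrom (default 4.5).
#' @param threshold Contact persistence threshold (default 0.75).
#' @param weighted Weighted betweenness for edge removal (default
#'   `TRUE`).
#' @param corr_floor Correlation magnitude floor (default `1e-6`).
#' @param align Superpose each half onto its own mean first (default
#'   `FALSE`; synthetic ensembles are already in a common frame).
#' @return List with `ari`, `q` (length 2), `n_communities` (length 2)
#'   and the two partitions.
#' @export
half_trajectory_convergence <- function(ensemble, nodes, cutoff = 4.5,
                                        threshold = 0.75, weighted = TRUE,
                                        corr_floor = 1e-6, align = FALSE) {
  n_frames <- dim(ensemble$xyz)[1]
  if (n_frames < 4) stop_dccnet("need at least 4 frames")
  half <- n_frames %/% 2
  parts <- lapply(list(1:half, (half + 1):n_frames), function(fr) {
    sub <- new_trajectory_ensemble(ensemble$topology,
                                   ensemble$xyz[fr, , , drop = FALSE])
    if (align) sub <- superpose(sub, nodes)
    p <- contact_persistence(sub, nodes, cutoff)
    ed <- contact_edges(p, threshold)
    cm <- correlation_matrix(sub, nodes)
    net <- build_network(ed, cm, floor = corr_floor)
    suppressWarnings(girvan_newman(net, weighted = weighted))
  })
  list(ari = partition_ari(parts[[1]]$membership, parts[[2]]$membership),
       q = c(parts[[1]]$q, parts[[2]]$q),
       n_communities = c(parts[[1]]$n_communities,
                         parts[[2]]$n_communities),
       partitions = list(parts[[1]], parts[[2]]))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement; 1 for identical partitions (including
#' the degenerate all-singleton / single-class cases, where the
#' chance-agreement correction is undefined).
#'
#' @param a,b Label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
partition_ari <- function(a, b) {
  if (length(a) != length(b)) stop_dccnet("partitions differ in length")
  r <- mclust::adjustedRandIndex(a, b)
  if (is.nan(r)) {
    # degenerate: both partitions all-singletons or all-one-class
    r <- if (identical(relabel(as.integer(factor(a))),
                       relabel(as.integer(factor(b))))) 1 else 0
  }
  r
}

#' Export a network or community graph
#'
#' @param x A `dynamic_network` or `community_graph`.
#' @param path Output path.
#' @param format `"graphml"` or `"json"` (node/edge lists).
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(x, path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (inherits(x, "dynamic_network")) {
    g <- network_igraph(x)
    nodes <- data.frame(id = seq_len(x$n_nodes), label = x$node_labels)
    edges <- x$edges
  } else if (inherits(x, "community_graph")) {
    g <- igraph::graph_from_data_frame(
      if (nrow(x$edges)) x$edges else data.frame(a = integer(), b = integer()),
      directed = FALSE,
      vertices = data.frame(name = x$communities$label,
                            size = x$communities$size))
    nodes <- x$communities
    edges <- x$edges
  } else stop_dccnet("unsupported graph object")
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    jsonlite::write_json(list(nodes = nodes, edges = edges), path,
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# -- internals ----------------------------------------------------------

network_igraph <- function(network) {
  g <- igraph::make_empty_graph(n = network$n_nodes, directed = FALSE)
  if (nrow(network$edges) > 0) {
    g <- igraph::add_edges(g, rbind(network$edges$i, network$edges$j))
    igraph::E(g)$w <- network$edges$w
  }
  g
}

new_partition <- function(membership, q, trace, memberships, weighted,
                          network) {
  structure(list(membership = as.integer(membership), q = q,
                 n_communities = length(unique(membership)),
                 trace = trace, memberships = memberships,
                 weighted = weighted,
                 node_labels = network$node_labels),
            class = "community_partition")
}

# canonical labels: first-seen order -> 1, 2, ...
relabel <- function(membership) {
  as.integer(match(membership, unique(membership)))
}

#' @export
print.community_partition <- function(x, ...) {
  cat("community_partition:", x$n_communities, "communities, Q =",
      round(x$q, 4), "(", if (x$weighted) "weighted" else "unweighted",
      "betweenness removal )\n")
  invisible(x)
}
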