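# Synthetic conformer ensembles with planted correlation-block
# communities and spatially consistent contacts.
#
# Displacements are axis-independent equicorrelated Gaussians: node i of
# block b moves as
#   d_i = sigma * (sqrt(inter)*G + sqrt(intra - inter)*B_b + sqrt(1 - intra)*e_i)
# per Cartesian axis, which yields pairwise correlation `intra` within a
# block and `inter` across blocks and is positive semi-definite by
# construction for 0 <= inter <= intra < 1.

#' Specification of a synthetic planted-community ensemble
#'
#' @param blocks Integer vector of block sizes (nodes per block), each
#'   `>= 2`.
#' @param intra_corr Target pairwise displacement correlation within a
#'   block, in `[0, 1)`.
#' @param inter_corr Target correlation between blocks, in
#'   `[0, intra_corr]`.
#' @param fluct_sigma Per-coordinate fluctuation scale in Angstrom
#'   (`> 0`).
#' @param n_frames Number of frames to sample (`>= 2`).
#' @param bridge_contacts Number of inter-block spatial bridges joining
#'   consecutive blocks.
#' @param chain_kind `"protein"` or `"nucleic"`, recycled per block.
#' @param seed Integer seed; all randomness flows from it.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(blocks, intra_corr = 0.8, inter_corr = 0.1,
                           fluct_sigma = 0.3, n_frames = 5000,
                           bridge_contacts = 1, chain_kind = "protein",
                           seed) {
  if (missing(seed)) stop_dccnet("an explicit integer seed is required")
  blocks <- as.integer(blocks)
  if (length(blocks) < 1 || any(blocks < 2)) {
    stop_dccnet("every block must contain at least 2 nodes")
  }
  if (!is.finite(intra_corr) || intra_corr < 0 || intra_corr >= 1) {
    stop_dccnet("intra_corr must lie in [0, 1)")
  }
  if (!is.finite(inter_corr) || inter_corr < 0 || inter_corr > intra_corr) {
    stop_dccnet("inter_corr must lie in [0, intra_corr]")
  }
  if (fluct_sigma <= 0) stop_dccnet("fluct_sigma must be positive")
  if (n_frames < 2) stop_dccnet("n_frames must be at least 2")
  if (bridge_contacts < 0) stop_dccnet("bridge_contacts must be >= 0")
  chain_kind <- rep_len(match.arg(chain_kind, c("protein", "nucleic"),
                                  several.ok = TRUE),
                        length(blocks))
  if (length(blocks) > 26) stop_dccnet("at most 26 blocks supported")
  structure(list(blocks = blocks, intra_corr = intra_corr,
                 inter_corr = inter_corr, fluct_sigma = fluct_sigma,
                 n_frames = as.integer(n_frames),
                 bridge_contacts = as.integer(bridge_contacts),
                 chain_kind = chain_kind, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Geometric constants of the bead layout (Angstrom). Each block is a
# compact face-centred-cubic cluster with nearest-neighbour spacing
# 4.0 A (inside the 4.5 A contact cutoff, with second neighbours at
# 5.66 A safely outside it); the non-bridge inter-block floor of 6 A
# sits well outside the cutoff under the default fluctuation scale.
NN_SPACING <- 4.0
FCC_U <- 4.0 / sqrt(2)   # lattice unit: neighbours differ by (+-1,+-1,0) perms
BRIDGE_GAP <- 4.0
BLOCK_GAP <- 12.0

#' Build the bead topology for a synthetic spec
#'
#' One residue per node: protein nodes expose a CA atom, nucleic nodes a
#' P atom. Each block occupies a compact face-centred-cubic cluster with
#' nearest-neighbour spacing 4.0 A; consecutive blocks are joined by
#' `bridge_contacts` node pairs placed 4.0 A apart, and all other
#' inter-block node pairs are more than 6 A apart. Chain IDs are
#' distinct per block. Residue numbers within a block are assigned so
#' that sequence neighbours are never spatial contacts, so the
#' sequence-adjacency exclusion of the contact map removes no planted
#' edge.
#'
#' @param spec A `synthetic_spec`.
#' @return A `structure_model` whose atoms are the bead representative
#'   atoms, with ground-truth block labels in
#'   `attr(, "block")`.
#' @export
build_bead_topology <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_blocks <- length(spec$blocks)
  bc <- spec$bridge_contacts
  n_in <- ifelse(seq_len(n_blocks) > 1, bc, 0L)
  n_out <- ifelse(seq_len(n_blocks) < n_blocks, bc, 0L)
  n_grid <- spec$blocks - n_in - n_out
  if (any(n_grid < 1)) {
    b <- which(n_grid < 1)[1]
    stop_dccnet("block ", b, " has too few nodes (", spec$blocks[b],
                ") for ", bc, " bridge contact(s) per side")
  }
  clusters <- lapply(n_grid, fcc_cluster)
  # align lattice parity of consecutive blocks so a donor at x = mx + 1
  # and an acceptor at x = min - 1 can share the same (y, z); a
  # y-translation by one lattice unit flips the (y, z) parity available
  # on the facing side and is rigid, hence otherwise harmless. Shifts
  # accumulate down the chain of blocks.
  if (n_blocks > 1 && bc > 0) {
    shift <- 0L
    for (b in 2:n_blocks) {
      shift <- (shift + max(clusters[[b - 1]][, 1]) -
                  min(clusters[[b]][, 1])) %% 2L
      clusters[[b]][, 2] <- clusters[[b]][, 2] + shift
    }
  }
  # joint donor/acceptor lattice sites for each consecutive block pair
  bridges <- if (n_blocks > 1 && bc > 0) {
    lapply(seq_len(n_blocks - 1), function(b) {
      bridge_sites(clusters[[b]], clusters[[b + 1]], bc, b)
    })
  } else list()
  coords <- vector("list", n_blocks)
  x_origin <- 0
  for (b in seq_len(n_blocks)) {
    cl <- clusters[[b]]
    acc <- if (n_in[b] > 0) bridges[[b - 1]]$acceptor else NULL
    don <- if (n_out[b] > 0) bridges[[b]]$donor else NULL
    sites <- rbind(acc, cl, don)
    pos <- sites * FCC_U
    pos[, 1] <- pos[, 1] + x_origin
    coords[[b]] <- pos
    if (b < n_blocks) {
      ncl <- clusters[[b + 1]]
      next_min <- min(ncl[, 1]) - (if (bc > 0) 1L else 0L)
      x_origin <- if (bc > 0) {
        # acceptor tip of the next block sits BRIDGE_GAP beyond our donor
        max(pos[, 1]) + BRIDGE_GAP - next_min * FCC_U
      } else {
        max(pos[, 1]) + BLOCK_GAP - next_min * FCC_U
      }
    }
  }
  block_of <- rep.int(seq_len(n_blocks), spec$blocks)
  pos <- do.call(rbind, coords)
  check_layout_separation(pos, block_of, bc)
  n <- nrow(pos)
  kind <- spec$chain_kind[block_of]
  # number residues within each block so that sequence neighbours are
  # never spatial contacts: the |delta resno| <= 1 exclusion of the
  # contact map then removes no planted intra-block edge
  resno <- unlist(lapply(seq_len(n_blocks), function(b) {
    nonadjacent_numbering(coords[[b]])
  }))
  atoms <- data.frame(
    record = "ATOM", serial = seq_len(n),
    name = ifelse(kind == "protein", "CA", "P"),
    altloc = " ",
    resname = ifelse(kind == "protein", "ALA", "DA"),
    chain = LETTERS[block_of], resno = resno, icode = " ",
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    occ = 1, b = 0,
    element = ifelse(kind == "protein", "C", "P"),
    het = FALSE, stringsAsFactors = FALSE)
  model <- new_structure_model(atoms)
  attr(model, "block") <- block_of
  model
}

#' Sample a synthetic ensemble and its ground truth
#'
#' Frames are the mean structure plus zero-mean Gaussian displacements
#' whose node-pair correlation is `intra_corr` within blocks and
#' `inter_corr` across blocks, with per-coordinate variance
#' `fluct_sigma^2`; the same correlation structure is applied
#' independently per Cartesian axis. Frames are i.i.d. draws, not a
#' time-correlated trajectory. Deterministic given `spec$seed`.
#'
#' @param spec A `synthetic_spec`.
#' @param topology Output of [build_bead_topology()] for the same spec
#'   (built automatically when omitted).
#' @return A list with `ensemble` (a `trajectory_ensemble`) and
#'   `ground_truth` (list: `partition`, `mean_structure`,
#'   `target_covariance`).
#' @export
sample_ensemble <- function(spec, topology = build_bead_topology(spec)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  block_of <- attr(topology, "block")
  n <- nrow(topology$atoms)
  if (is.null(block_of) || n != sum(spec$blocks)) {
    stop_dccnet("topology does not match spec")
  }
  rho_w <- spec$intra_corr
  rho_b <- spec$inter_corr
  # PSD check of the implied block covariance (guaranteed by the
  # decomposition, verified defensively block-pair-wise)
  if (rho_b > rho_w) {
    stop_dccnet("non-PSD covariance: inter-block correlation between blocks ",
                1, " and ", 2, " exceeds the intra-block correlation")
  }
  a <- sqrt(rho_b)            # global factor loading
  bld <- sqrt(rho_w - rho_b)  # block factor loading
  cn <- sqrt(1 - rho_w)       # idiosyncratic loading
  sg <- spec$fluct_sigma
  n_frames <- spec$n_frames
  n_blocks <- length(spec$blocks)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)
  mean_xyz <- as.matrix(topology$atoms[, c("x", "y", "z")])
  xyz <- array(NA_real_, dim = c(n_frames, n, 3))
  for (ax in 1:3) {
    G <- rnorm(n_frames)
    B <- matrix(rnorm(n_frames * n_blocks), n_frames, n_blocks)
    E <- matrix(rnorm(n_frames * n), n_frames, n)
    d <- sg * (a * G + bld * B[, block_of, drop = FALSE] + cn * E)
    xyz[, , ax] <- sweep(d, 2, mean_xyz[, ax], "+")
  }
  target <- matrix(rho_b, n, n)
  for (b in seq_len(n_blocks)) {
    idx <- which(block_of == b)
    target[idx, idx] <- rho_w
  }
  diag(target) <- 1
  target <- sg^2 * target
  list(ensemble = new_trajectory_ensemble(topology, xyz),
       ground_truth = list(partition = block_of,
                           mean_structure = mean_xyz,
                           target_covariance = target))
}

#' Write ground-truth block labels as a two-column table
#'
#' @param ground_truth Ground truth from [sample_ensemble()].
#' @param nodes Node set of the bead topology.
#' @param path Output path (plain text, `node_id` and `label`).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, nodes, path) {
  df <- data.frame(node_id = paste0(nodes$chain, ":", nodes$resno),
                   label = ground_truth$partition)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- internals ----------------------------------------------------------

# The 12 fcc lattice neighbours of a site (permutations of (+-1,+-1,0)).
FCC_STEPS <- rbind(
  c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0),
  c(1, 0, 1), c(1, 0, -1), c(-1, 0, 1), c(-1, 0, -1),
  c(0, 1, 1), c(0, 1, -1), c(0, -1, 1), c(0, -1, -1))

fcc_neighbors <- function(s) {
  sweep(FCC_STEPS, 2, s, "+")
}

site_key <- function(m) paste(m[, 1], m[, 2], m[, 3])

# Compact connected fcc cluster of n sites, grown greedily from the
# origin: each step adds the frontier site with the most contacts to
# the cluster built so far (densest attachment), breaking ties by
# distance to the origin and then lexicographically. Dense attachment
# keeps the intra-block contact graph well knit, so planted blocks are
# not themselves split by modularity optimization.
fcc_cluster <- function(n) {
  cl <- matrix(0L, nrow = n, ncol = 3)
  if (n == 1) return(cl)
  member <- "0 0 0"
  cand <- fcc_neighbors(c(0L, 0L, 0L))
  for (k in 2:n) {
    links <- vapply(seq_len(nrow(cand)), function(r) {
      sum(site_key(fcc_neighbors(cand[r, ])) %in% member)
    }, integer(1))
    sc <- rowSums(cand^2)
    ord <- order(-links, sc, cand[, 1], cand[, 2], cand[, 3])
    pick <- cand[ord[1], ]
    cl[k, ] <- pick
    member <- c(member, paste(pick, collapse = " "))
    pool <- rbind(cand[-ord[1], , drop = FALSE], fcc_neighbors(pick))
    keys <- site_key(pool)
    pool <- pool[!duplicated(keys) & !(keys %in% member), , drop = FALSE]
    cand <- pool
  }
  cl
}

# Joint donor (block A, +x face) and acceptor (block B, -x face) lattice
# sites for `bc` bridges. A donor protrudes one lattice layer beyond the
# face and must touch the cluster (up to four anchors, so bridge nodes
# are never weakly attached pendants); the acceptor mirrors it at the
# same (y, z) so the bridge vector is purely +x with length 4.0 A.
# Selected sites keep >= 2 lattice units of (y, z) separation so
# non-partner bridge pairs stay beyond 6 A.
bridge_sites <- function(cl_a, cl_b, bc, pair_index) {
  cand_a <- protrusion_sites(cl_a, "max")
  cand_b <- protrusion_sites(cl_b, "min")
  joint <- merge(cand_a$yz, cand_b$yz, by = c("y", "z"))
  if (nrow(joint) > 0) {
    # prefer bridge nodes with several anchors on both sides: a bridge
    # node hanging off a single anchor can be cut away from its own
    # block by betweenness-based removal
    score <- pmin(joint$anchors.x, joint$anchors.y)
    joint <- joint[order(-score, abs(joint$y) + abs(joint$z), joint$y,
                         joint$z), , drop = FALSE]
    chosen <- list()
    for (r in seq_len(nrow(joint))) {
      p <- c(joint$y[r], joint$z[r])
      ok <- all(vapply(chosen, function(q) sum((p - q)^2) >= 4, logical(1)))
      if (ok) chosen[[length(chosen) + 1]] <- p
      if (length(chosen) == bc) break
    }
  } else chosen <- list()
  if (length(chosen) < bc) {
    stop_dccnet("layout infeasible: blocks ", pair_index, " and ",
                pair_index + 1, " cannot host ", bc,
                " separated bridge contact(s); enlarge the blocks or ",
                "reduce bridge_contacts")
  }
  yz <- do.call(rbind, chosen)
  list(donor = cbind(max(cl_a[, 1]) + 1L, yz[, 1], yz[, 2]),
       acceptor = cbind(min(cl_b[, 1]) - 1L, yz[, 1], yz[, 2]))
}

# Candidate (y, z) positions for a protruding bridge site one lattice
# layer beyond the extreme x face of a cluster, with at least one
# cluster anchor among its lattice neighbours.
protrusion_sites <- function(cl, side = c("max", "min")) {
  side <- match.arg(side)
  xf <- if (side == "max") max(cl[, 1]) + 1L else min(cl[, 1]) - 1L
  keys <- site_key(cl)
  face <- cl[cl[, 1] == (if (side == "max") xf - 1L else xf + 1L), ,
             drop = FALSE]
  cand <- unique(do.call(rbind, lapply(seq_len(nrow(face)), function(r) {
    nb <- fcc_neighbors(face[r, ])
    nb[nb[, 1] == xf, , drop = FALSE]
  })))
  anchors <- vapply(seq_len(nrow(cand)), function(r) {
    nb <- fcc_neighbors(cand[r, ])
    sum(site_key(nb) %in% keys)
  }, integer(1))
  cand <- cand[anchors > 0, , drop = FALSE]
  list(yz = data.frame(y = cand[, 2], z = cand[, 3],
                       anchors = anchors[anchors > 0]))
}

# Residue numbers for the nodes at `pos` such that consecutive numbers
# are farther apart than the contact cutoff wherever geometrically
# possible (greedy over all starting nodes; tiny blocks where no such
# numbering exists fall back to layout order).
nonadjacent_numbering <- function(pos, cutoff = 4.5) {
  m <- nrow(pos)
  if (m <= 2) return(seq_len(m))
  adj <- cross_dist2(pos, pos) <= cutoff^2 + 1e-9
  for (start in seq_len(m)) {
    ord <- integer(m)
    used <- logical(m)
    ord[1] <- start
    used[start] <- TRUE
    ok <- TRUE
    for (k in 2:m) {
      cand <- which(!used & !adj[ord[k - 1], ])
      if (length(cand) == 0) {
        ok <- FALSE
        break
      }
      ord[k] <- cand[1]
      used[cand[1]] <- TRUE
    }
    if (ok) {
      resno <- integer(m)
      resno[ord] <- seq_len(m)
      return(resno)
    }
  }
  seq_len(m)
}

# Verify inter-block separation: exactly `bc` pairs at <= 4.5 A between
# consecutive blocks, all other inter-block pairs > 6 A.
check_layout_separation <- function(pos, block_of, bc) {
  d2 <- cross_dist2(pos, pos)
  same <- outer(block_of, block_of, "==")
  consec <- abs(outer(block_of, block_of, "-")) == 1
  inter <- !same & upper.tri(d2)
  near <- inter & d2 <= 4.5^2 + 1e-9
  n_bridges_expected <- bc * max(0, length(unique(block_of)) - 1)
  if (sum(near & consec) != n_bridges_expected || any(near & !consec)) {
    stop_dccnet("layout infeasible: unintended inter-block contacts ",
                "(over-dense layout)")
  }
  mid <- inter & !near
  if (any(d2[mid] <= 36)) {
    stop_dccnet("layout infeasible: non-bridge inter-block pair within 6 A")
  }
  invisible(TRUE)
}
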