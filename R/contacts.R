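# Persistence-filtered contact maps and persistent-contact
# classification.
#
# A residue pair is "in contact" in a frame when the minimum
# heavy-atom distance between the two residues is within the cutoff;
# hydrogens are ignored throughout. Same-chain sequence neighbours
# (|delta resno| <= 1) are excluded from the map; inter-chain pairs
# never are.

#' Fraction of frames each residue pair spends in contact
#'
#' @param ensemble A `trajectory_ensemble`.
#' @param nodes A `node_set` defining the residues considered.
#' @param cutoff Contact distance cutoff in Angstrom (default 4.5).
#' @return An `N x N` matrix of class `contact_persistence` with
#'   entries in `[0, 1]` (diagonal 0). Sequence-adjacent pairs are
#'   stored as 0 and flagged in `attr(, "excluded")`;
#'   `attr(, "cutoff")` records the cutoff.
#' @export
contact_persistence <- function(ensemble, nodes, cutoff = 4.5) {
  atoms <- ensemble$topology$atoms
  n <- nrow(nodes)
  res_atoms <- residue_heavy_atoms(atoms, nodes)
  n_frames <- dim(ensemble$xyz)[1]
  p <- matrix(0, n, n)
  excluded <- matrix(FALSE, n, n)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (nodes$chain[i] == nodes$chain[j] &&
            abs(nodes$resno[i] - nodes$resno[j]) <= 1) {
          excluded[i, j] <- excluded[j, i] <- TRUE
          next
        }
        dmin2 <- min_pair_dist2(ensemble$xyz, res_atoms[[i]], res_atoms[[j]])
        p[i, j] <- p[j, i] <- sum(dmin2 <= cutoff^2) / n_frames
      }
    }
  }
  dimnames(p) <- list(node_labels(nodes), node_labels(nodes))
  attr(p, "excluded") <- excluded
  attr(p, "cutoff") <- cutoff
  class(p) <- c("contact_persistence", class(p))
  p
}

#' Contact edges from a persistence map
#'
#' Pairs in contact for at least `threshold` of the frames (inclusive
#' boundary: persistence exactly at the threshold is in contact).
#'
#' @param persistence A `contact_persistence` matrix.
#' @param threshold Persistence threshold in `[0, 1]` (default 0.75).
#' @return Data frame of edges `i`, `j` (node indices, `i < j`,
#'   lexicographic order) and `p`.
#' @export
contact_edges <- function(persistence, threshold = 0.75) {
  if (threshold < 0 || threshold > 1) {
    stop_dccnet("threshold must lie in [0, 1]")
  }
  excluded <- attr(persistence, "excluded")
  p <- unclass(persistence)
  keep <- upper.tri(p) & p >= threshold
  if (!is.null(excluded)) keep <- keep & !excluded
  idx <- which(keep, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], p = p[keep])
  df <- df[order(df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Classify persistent residue contacts
#'
#' Per residue pair and frame, a hydrogen-bond/salt-bridge event occurs
#' when any inter-residue N/O-N/O atom pair is within `hbond_cutoff`,
#' and a hydrophobic event when any apolar carbon pair is within
#' `hydrophobic_cutoff`. Contacts observed in more than `min_fraction`
#' of frames (strict inequality) are reported, classed by the
#' higher-fraction event type (ties go to `hbond_saltbridge`). Apolar
#' carbons are identified by a name heuristic: a carbon is polar when
#' its residue carries an N/O atom at the same side-chain position
#' letter (and backbone C/CA are always polar).
#'
#' @param ensemble A full-atom `trajectory_ensemble` (element fields
#'   required).
#' @param nodes A `node_set` defining the residues considered.
#' @param hbond_cutoff N/O-N/O cutoff in Angstrom (default 3.5).
#' @param hydrophobic_cutoff C-C cutoff in Angstrom (default 4.5).
#' @param min_fraction Persistence floor; only contacts with event
#'   fraction strictly greater are kept (default 0.60).
#' @return Data frame with columns `chain_a`, `resno_a`, `chain_b`,
#'   `resno_b`, `class`, `fraction`, `cutoff`.
#' @export
classify_persistent_contacts <- function(ensemble, nodes,
                                         hbond_cutoff = 3.5,
                                         hydrophobic_cutoff = 4.5,
                                         min_fraction = 0.60) {
  atoms <- ensemble$topology$atoms
  if (any(!nzchar(trimws(atoms$element)))) {
    stop_dccnet("element fields missing from the model")
  }
  n <- nrow(nodes)
  n_frames <- dim(ensemble$xyz)[1]
  rid <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "\r")
  out <- list()
  polar_sets <- lapply(seq_len(n), function(i) {
    rows <- which(rid == rid[nodes$atom[i]])
    rows[atoms$element[rows] %in% c("N", "O")]
  })
  apolar_sets <- lapply(seq_len(n), function(i) {
    rows <- which(rid == rid[nodes$atom[i]])
    rows[apolar_carbon(atoms$name[rows], atoms$element[rows])]
  })
  for (i in seq_len(max(0, n - 1))) {
    for (j in (i + 1):n) {
      if (nodes$chain[i] == nodes$chain[j] &&
          abs(nodes$resno[i] - nodes$resno[j]) <= 1) next
      f_hb <- event_fraction(ensemble$xyz, polar_sets[[i]], polar_sets[[j]],
                             hbond_cutoff, n_frames)
      f_ph <- event_fraction(ensemble$xyz, apolar_sets[[i]], apolar_sets[[j]],
                             hydrophobic_cutoff, n_frames)
      if (max(f_hb, f_ph) > min_fraction) {
        is_hb <- f_hb >= f_ph
        out[[length(out) + 1]] <- data.frame(
          chain_a = nodes$chain[i], resno_a = nodes$resno[i],
          chain_b = nodes$chain[j], resno_b = nodes$resno[j],
          class = if (is_hb) "hbond_saltbridge" else "hydrophobic",
          fraction = if (is_hb) f_hb else f_ph,
          cutoff = if (is_hb) hbond_cutoff else hydrophobic_cutoff,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chain_a = character(), resno_a = integer(),
                      chain_b = character(), resno_b = integer(),
                      class = character(), fraction = double(),
                      cutoff = double(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a persistence map as a triplet table
#'
#' @param persistence A `contact_persistence` matrix.
#' @param path Output path (TSV: `i`, `j`, `p`).
#' @return `path`, invisibly.
#' @export
write_persistence <- function(persistence, path) {
  excluded <- attr(persistence, "excluded")
  p <- unclass(persistence)
  keep <- upper.tri(p)
  if (!is.null(excluded)) keep <- keep & !excluded
  idx <- which(keep, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], p = p[keep])
  df <- df[order(df$i, df$j), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- internals ----------------------------------------------------------

residue_heavy_atoms <- function(atoms, nodes) {
  rid <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "\r")
  heavy <- atoms$element != "H"
  lapply(seq_len(nrow(nodes)), function(i) {
    rows <- which(rid == rid[nodes$atom[i]] & heavy)
    rows
  })
}

# Per-frame minimum squared distance between two atom sets.
min_pair_dist2 <- function(xyz, rows_a, rows_b) {
  n_frames <- dim(xyz)[1]
  dmin2 <- rep(Inf, n_frames)
  for (a in rows_a) {
    for (b in rows_b) {
      d2 <- (xyz[, a, 1] - xyz[, b, 1])^2 +
        (xyz[, a, 2] - xyz[, b, 2])^2 +
        (xyz[, a, 3] - xyz[, b, 3])^2
      dmin2 <- pmin(dmin2, d2)
    }
  }
  dmin2
}

event_fraction <- function(xyz, rows_a, rows_b, cutoff, n_frames) {
  if (length(rows_a) == 0 || length(rows_b) == 0) return(0)
  sum(min_pair_dist2(xyz, rows_a, rows_b) <= cutoff^2) / n_frames
}

# Apolar-carbon heuristic. Side-chain names follow the PDB remoteness
# convention (A, B, G, D, E, Z, H in name position 2), and a carbon at
# remoteness L is bonded to heteroatoms named with the next letter
# (e.g. SER CB-OG, GLU CD-OE1, LYS CE-NZ). Backbone C and CA are bonded
# to the carbonyl O and amide N and are always polar.
REMOTENESS <- c("A", "B", "G", "D", "E", "Z", "H")

apolar_carbon <- function(names, elements) {
  het_pos <- substr(names[elements %in% c("N", "O")], 2, 2)
  vapply(seq_along(names), function(k) {
    if (elements[k] != "C") return(FALSE)
    nm <- names[k]
    if (nm %in% c("C", "CA")) return(FALSE)  # backbone: bonded to O / N
    pos <- substr(nm, 2, 2)
    r <- match(pos, REMOTENESS)
    if (is.na(r)) return(FALSE)  # unusual name: assume polar
    if (r == length(REMOTENESS)) return(TRUE)
    !any(het_pos == REMOTENESS[r + 1])
  }, logical(1))
}
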