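# Frame superposition and fluctuation statistics: RMSF, B-factors and
# the linear dynamic cross-correlation matrix (DCCM) over network nodes.

#' Superpose ensemble frames by rigid-body least squares
#'
#' Each frame is rotated and translated (Kabsch, no scaling) to
#' minimize the RMSD of the fit-node representative atoms to the
#' reference. With `reference = "mean"` the mean structure is used and
#' the fit is iterated twice (align, recompute mean, align again).
#'
#' @param ensemble A `trajectory_ensemble`.
#' @param nodes A `node_set`; fit uses all its representative atoms
#'   (restrict the node set to restrict the fit).
#' @param reference `"mean"` (default) or a frame index.
#' @return The superposed `trajectory_ensemble`.
#' @export
superpose <- function(ensemble, nodes, reference = "mean") {
  xyz <- ensemble$xyz
  n_frames <- dim(xyz)[1]
  if (n_frames < 2) stop_dccnet("superposition needs at least 2 frames")
  idx <- nodes$atom
  if (length(idx) < 1) stop_dccnet("at least one fit node required")
  check_fit_atoms(xyz[1, idx, , drop = FALSE])
  if (identical(reference, "mean")) {
    for (pass in 1:2) {
      ref <- apply(xyz[, idx, , drop = FALSE], c(2, 3), mean)
      xyz <- fit_frames(xyz, idx, ref)
    }
  } else {
    f <- as.integer(reference)
    if (is.na(f) || f < 1 || f > n_frames) {
      stop_dccnet("reference frame index out of range")
    }
    ref <- xyz[f, idx, ]
    xyz <- fit_frames(xyz, idx, ref)
  }
  new_trajectory_ensemble(ensemble$topology, xyz)
}

#' Per-node fluctuations and B-factors
#'
#' Mean-square fluctuation of each node's representative atom about its
#' ensemble-mean position, with the crystallographic conversion
#' `B = (8 pi^2 / 3) * MSF`.
#'
#' @param ensemble A superposed `trajectory_ensemble`.
#' @param nodes A `node_set`.
#' @return A `fluctuation_profile` data frame: `chain`, `resno`, `msf`
#'   (A^2), `rmsf` (A), `b` (A^2).
#' @export
rmsf_bfactor <- function(ensemble, nodes) {
  xyz <- ensemble$xyz[, nodes$atom, , drop = FALSE]
  mu <- apply(xyz, c(2, 3), mean)
  dev2 <- sweep(xyz, c(2, 3), mu)^2
  msf <- apply(dev2, 2, sum) / dim(xyz)[1]
  out <- data.frame(chain = nodes$chain, resno = nodes$resno,
                    msf = msf, rmsf = sqrt(msf), b = (8 * pi^2 / 3) * msf)
  class(out) <- c("fluctuation_profile", class(out))
  out
}

#' Node-node dynamic cross-correlation matrix
#'
#' Linear DCCM over representative-atom displacements:
#' `c_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>)`, with `dr` the
#' instantaneous minus mean position. A zero-variance node gets zero
#' off-diagonal entries (diagonal 1) with a warning so static nodes do
#' not poison the matrix.
#'
#' @param ensemble A superposed `trajectory_ensemble` with `F >= 2`.
#' @param nodes A `node_set`.
#' @return An `N x N` matrix of class `correlation_matrix`, node order
#'   following `nodes`.
#' @export
correlation_matrix <- function(ensemble, nodes) {
  xyz <- ensemble$xyz[, nodes$atom, , drop = FALSE]
  n_frames <- dim(xyz)[1]
  if (n_frames < 2) stop_dccnet("correlation needs at least 2 frames")
  n <- dim(xyz)[2]
  cov3 <- matrix(0, n, n)
  for (ax in 1:3) {
    d <- xyz[, , ax]
    d <- sweep(d, 2, colMeans(d))
    cov3 <- cov3 + crossprod(d) / n_frames
  }
  v <- diag(cov3)
  zero <- v < 1e-12
  if (any(zero)) {
    warning(sum(zero), " zero-variance node(s); their correlations set to 0",
            call. = FALSE)
    v[zero] <- 1
  }
  cmat <- cov3 / sqrt(outer(v, v))
  if (any(zero)) {
    cmat[zero, ] <- 0
    cmat[, zero] <- 0
  }
  diag(cmat) <- 1
  dimnames(cmat) <- list(node_labels(nodes), node_labels(nodes))
  class(cmat) <- c("correlation_matrix", class(cmat))
  cmat
}

#' Write a correlation matrix as plain text
#'
#' @param cmat A `correlation_matrix`.
#' @param path Output path.
#' @param format `"matrix"` (square, whitespace-separated) or
#'   `"triplet"` (`i`, `j`, `c_ij` table, upper triangle).
#' @return `path`, invisibly.
#' @export
write_correlation <- function(cmat, path, format = c("matrix", "triplet")) {
  format <- match.arg(format)
  if (format == "matrix") {
    utils::write.table(format(unclass(cmat), digits = 10), path,
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    ut <- which(upper.tri(cmat), arr.ind = TRUE)
    df <- data.frame(i = ut[, 1], j = ut[, 2], c = cmat[ut])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

node_labels <- function(nodes) {
  paste0(nodes$chain, ":", nodes$resno,
         ifelse(trimws(nodes$icode %||% "") == "", "",
                trimws(nodes$icode %||% "")))
}

# -- internals ----------------------------------------------------------

check_fit_atoms <- function(coords) {
  p <- matrix(coords, ncol = 3)
  if (nrow(p) >= 3) {
    pc <- sweep(p, 2, colMeans(p))
    if (qr(pc)$rank >= 2) return(invisible(TRUE))
  }
  stop_dccnet("rotation under-determined: need at least 3 non-collinear ",
              "fit atoms")
}

# Kabsch rotation bringing P onto Q (both n x 3, n >= 3 non-collinear)
kabsch <- function(p, q) {
  cp <- colMeans(p)
  cq <- colMeans(q)
  h <- crossprod(sweep(p, 2, cp), sweep(q, 2, cq))
  s <- svd(h)
  d <- sign(det(tcrossprod(s$v, s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = r, center_p = cp, center_q = cq)
}

fit_frames <- function(xyz, idx, ref) {
  n_frames <- dim(xyz)[1]
  for (f in seq_len(n_frames)) {
    k <- kabsch(xyz[f, idx, ], ref)
    moved <- sweep(xyz[f, , ], 2, k$center_p) %*% t(k$rotation)
    xyz[f, , ] <- sweep(moved, 2, k$center_q, "+")
  }
  xyz
}
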