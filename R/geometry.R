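# Structure and ensemble geometry: atom-pair distances, lysine reach
# scans, duplex kink angles, Shrake-Rupley solvent-accessible surface
# area and buried interface fractions.

# van der Waals radii (Angstrom) used for SASA
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
VDW_DEFAULT <- 1.70

#' Parse a `chain:resno[:atom]` selection string
#'
#' @param sel Selection string, e.g. `"A:12:CA"`; the atom part is
#'   optional. A list/data frame with `chain`, `resno` (and optional
#'   `name`) is passed through.
#' @return List with `chain`, `resno`, `name` (possibly `NA`).
#' @export
parse_selection <- function(sel) {
  if (is.list(sel)) {
    return(list(chain = sel$chain, resno = as.integer(sel$resno),
                name = sel$name %||% NA_character_))
  }
  parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2) stop_dccnet("selection must be chain:resno[:atom]")
  list(chain = parts[1], resno = as.integer(parts[2]),
       name = if (length(parts) >= 3) parts[3] else NA_character_)
}

resolve_selection <- function(model, sel, require_one = TRUE) {
  s <- parse_selection(sel)
  a <- model$atoms
  hit <- which(a$chain == s$chain & a$resno == s$resno &
                 (is.na(s$name) | trimws(a$name) == s$name))
  if (length(hit) == 0) stop_dccnet("selection matches no atom: ",
                                    s$chain, ":", s$resno,
                                    if (!is.na(s$name)) paste0(":", s$name))
  if (require_one && length(hit) > 1) {
    stop_dccnet("selection is ambiguous (", length(hit), " atoms): ",
                s$chain, ":", s$resno)
  }
  hit
}

#' Distance between two selected atoms
#'
#' @param x A `structure_model` or `trajectory_ensemble`.
#' @param sel_a,sel_b Selections resolving to exactly one atom each
#'   (see [parse_selection()]).
#' @return For a model, a single distance in Angstrom. For an ensemble,
#'   the per-frame distances with a `summary` attribute (min, mean,
#'   max).
#' @export
pair_distance <- function(x, sel_a, sel_b) {
  if (inherits(x, "structure_model")) {
    ia <- resolve_selection(x, sel_a)
    ib <- resolve_selection(x, sel_b)
    p <- as.matrix(x$atoms[c(ia, ib), c("x", "y", "z")])
    return(sqrt(sum((p[1, ] - p[2, ])^2)))
  }
  ia <- resolve_selection(x$topology, sel_a)
  ib <- resolve_selection(x$topology, sel_b)
  d <- sqrt((x$xyz[, ia, 1] - x$xyz[, ib, 1])^2 +
              (x$xyz[, ia, 2] - x$xyz[, ib, 2])^2 +
              (x$xyz[, ia, 3] - x$xyz[, ib, 3])^2)
  attr(d, "summary") <- c(min = min(d), mean = mean(d), max = max(d))
  d
}

#' Scan for lysines within reach of a reference atom
#'
#' Reports every LYS residue on the target chains whose NZ atom (the
#' chemically attacked amine; CA fallback when NZ is absent, flagged)
#' comes strictly within `cutoff` of the reference atom in at least one
#' conformer. The union across the ensemble is reported with each
#' residue's minimum distance.
#'
#' @param x A `structure_model` or `trajectory_ensemble`.
#' @param target_chains Character vector of chain IDs to scan.
#' @param reference Selection resolving to one atom (e.g. an E2 active
#'   site residue atom).
#' @param cutoff Reach cutoff in Angstrom, strict inequality (default
#'   12).
#' @return A `reach_report` data frame: `chain`, `resno`, `min_dist`,
#'   `atom_used`, `n_frames_in_range`; `attr(, "cutoff")` and
#'   `attr(, "reference")` record the scan parameters.
#' @export
lysine_reach_scan <- function(x, target_chains, reference, cutoff = 12) {
  model <- if (inherits(x, "trajectory_ensemble")) x$topology else x
  xyz <- if (inherits(x, "trajectory_ensemble")) {
    x$xyz
  } else {
    array(as.matrix(model$atoms[, c("x", "y", "z")]),
          dim = c(1, nrow(model$atoms), 3))
  }
  iref <- resolve_selection(model, reference)
  a <- model$atoms
  lys <- which(trimws(a$resname) == "LYS" & a$chain %in% target_chains)
  if (length(lys) == 0) {
    warning("no LYS residues on target chain(s)", call. = FALSE)
    out <- data.frame(chain = character(), resno = integer(),
                      min_dist = double(), atom_used = character(),
                      n_frames_in_range = integer())
    attr(out, "cutoff") <- cutoff
    class(out) <- c("reach_report", class(out))
    return(out)
  }
  rid <- paste(a$chain, a$resno, a$icode, sep = "\r")
  res <- unique(rid[lys])
  rows <- lapply(res, function(r) {
    ra <- which(rid == r)
    nz <- ra[trimws(a$name[ra]) == "NZ"]
    used <- if (length(nz) > 0) "NZ" else "CA"
    ai <- if (length(nz) > 0) nz[1] else ra[trimws(a$name[ra]) == "CA"][1]
    if (is.na(ai)) return(NULL)
    d <- sqrt((xyz[, ai, 1] - xyz[, iref, 1])^2 +
                (xyz[, ai, 2] - xyz[, iref, 2])^2 +
                (xyz[, ai, 3] - xyz[, iref, 3])^2)
    data.frame(chain = a$chain[ra[1]], resno = a$resno[ra[1]],
               min_dist = min(d), atom_used = used,
               n_frames_in_range = sum(d < cutoff),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$min_dist < cutoff, , drop = FALSE]  # strict "< cutoff"
  out <- out[order(out$chain, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  if (any(out$atom_used != "NZ")) {
    warning("CA fallback used for ", sum(out$atom_used != "NZ"),
            " lysine(s) lacking NZ", call. = FALSE)
  }
  attr(out, "cutoff") <- cutoff
  attr(out, "reference") <- reference
  class(out) <- c("reach_report", class(out))
  out
}

#' Kink angle between two arms of a duplex
#'
#' Each arm's axis is the first principal direction of its backbone
#' atom coordinates (P atoms, with CA fallback), oriented to point away
#' from the junction (away from the arm's atom nearest to the other
#' arm). The reported angle is the angle between the two away-pointing
#' axes, so a straight duplex gives 180 degrees and the kink magnitude
#' is `180 - angle`.
#'
#' @param model A `structure_model`.
#' @param arm_a,arm_b Lists with `chain` and `resno` (vector of residue
#'   numbers) identifying each arm; each arm must supply at least 3
#'   backbone atoms.
#' @return Angle in degrees.
#' @export
duplex_kink_angle <- function(model, arm_a, arm_b) {
  pa <- arm_backbone_coords(model, arm_a)
  pb <- arm_backbone_coords(model, arm_b)
  if (nrow(pa) < 3 || nrow(pb) < 3) {
    stop_dccnet("each arm needs at least 3 backbone (P or CA) atoms")
  }
  axis_away <- function(p, other) {
    ax <- svd(sweep(p, 2, colMeans(p)))$v[, 1]
    d2 <- cross_dist2(p, other)
    junction <- p[which(d2 == min(d2), arr.ind = TRUE)[1, 1], ]
    if (sum(ax * (colMeans(p) - junction)) < 0) ax <- -ax
    ax
  }
  ax_a <- axis_away(pa, pb)
  ax_b <- axis_away(pb, pa)
  cosang <- sum(ax_a * ax_b)
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Quasi-uniform points (Fibonacci spiral) on each atom's
#' probe-expanded sphere; the accessible fraction is the share of
#' points not inside any neighbour's expanded sphere. Radii: C 1.70,
#' N 1.55, O 1.52, S 1.80, P 1.80, H 1.20, other 1.70 A. Hydrogens are
#' included when present.
#'
#' @param model A `structure_model`.
#' @param probe Probe radius in Angstrom (default 1.4).
#' @param n_points Sphere points per atom (default 960).
#' @return List with `atom_area` (per-atom areas, A^2) and `residue`
#'   (data frame `chain`, `resno`, `area`); `total` is the summed area.
#' @export
sasa <- function(model, probe = 1.4, n_points = 960) {
  a <- model$atoms
  n <- nrow(a)
  if (n == 0) stop_dccnet("model has no atoms")
  radii <- unname(VDW_RADII[a$element])
  radii[is.na(radii)] <- VDW_DEFAULT
  rp <- radii + probe
  xyz <- as.matrix(a[, c("x", "y", "z")])
  sph <- fibonacci_sphere(n_points)
  area <- numeric(n)
  d2 <- cross_dist2(xyz, xyz)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rp[i] + rp)^2 & seq_len(n) != i)
    pts <- sweep(sph * rp[i], 2, xyz[i, ], "+")
    if (length(nb) > 0) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
          (pts[, 3] - xyz[j, 3])^2
        acc <- acc & dj2 > rp[j]^2
        if (!any(acc)) break
      }
      frac <- sum(acc) / n_points
    } else {
      frac <- 1
    }
    area[i] <- frac * 4 * pi * rp[i]^2
  }
  rid <- paste(a$chain, a$resno, a$icode, sep = "\r")
  agg <- rowsum(area, rid, reorder = FALSE)
  first <- !duplicated(rid)
  residue <- data.frame(chain = a$chain[first], resno = a$resno[first],
                        area = agg[, 1], row.names = NULL)
  list(atom_area = area, residue = residue, total = sum(area))
}

#' Buried surface fraction of a component within a complex
#'
#' `fraction = (SASA of the component alone - SASA of the component in
#' the complex) / SASA alone`. The per-partner decomposition removes
#' one partner at a time: a partner's share is the component SASA
#' restored by its removal, normalized over partners.
#'
#' @param model A `structure_model` of the full complex.
#' @param component Chain ID(s) forming the component.
#' @param partners Chain IDs considered as partners (default: all
#'   other chains).
#' @param probe,n_points Passed to [sasa()].
#' @return List with `fraction`, `sasa_alone`, `sasa_complex` and
#'   `partner_share` (named, normalized over partners).
#' @export
buried_fraction <- function(model, component, partners = NULL,
                            probe = 1.4, n_points = 960) {
  a <- model$atoms
  comp_rows <- which(a$chain %in% component)
  if (length(comp_rows) == 0) stop_dccnet("component matches no atoms")
  partners <- partners %||% setdiff(unique(a$chain), component)
  alone <- sasa(subset_model(model, comp_rows), probe, n_points)$total
  if (alone <= 0) stop_dccnet("component SASA alone is zero")
  in_complex <- sum(sasa(model, probe, n_points)$atom_area[comp_rows])
  share <- setNames(numeric(length(partners)), partners)
  for (p in partners) {
    keep <- which(!(a$chain %in% p))
    s <- sasa(subset_model(model, keep), probe, n_points)
    share[p] <- sum(s$atom_area[match(comp_rows, keep)]) - in_complex
  }
  share <- pmax(share, 0)
  if (sum(share) > 0) share <- share / sum(share)
  list(fraction = (alone - in_complex) / alone,
       sasa_alone = alone, sasa_complex = in_complex,
       partner_share = share)
}

# -- internals ----------------------------------------------------------

arm_backbone_coords <- function(model, arm) {
  a <- model$atoms
  rows <- which(a$chain == arm$chain & a$resno %in% arm$resno &
                  trimws(a$name) %in% c("P", "CA"))
  # prefer P when both present within a residue
  rid <- paste(a$chain[rows], a$resno[rows], a$icode[rows], sep = "\r")
  keep <- unlist(lapply(split(rows, rid), function(rr) {
    pp <- rr[trimws(a$name[rr]) == "P"]
    if (length(pp) > 0) pp[1] else rr[1]
  }), use.names = FALSE)
  as.matrix(a[keep, c("x", "y", "z"), drop = FALSE])
}

subset_model <- function(model, rows) {
  new_structure_model(model$atoms[rows, , drop = FALSE])
}

# Deterministic quasi-uniform unit-sphere points (Fibonacci spiral).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}
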