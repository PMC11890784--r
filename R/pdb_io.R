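# Structure and ensemble I/O: fixed-column PDB dialect, multi-model
# ensembles, network-node selection and per-residue B-factor writing.
#
# Residue identity is always (chain, resno, icode); numbering is preserved
# verbatim and never renumbered. Only the multi-model PDB dialect is
# supported for ensembles; bonds are never inferred.

AMINO_RESNAMES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  # common variants/protonation states and seleno residues
  "MSE", "SEC", "PYL", "HSD", "HSE", "HSP", "HID", "HIE", "HIP", "CYX",
  "CYM", "ASH", "GLH", "LYN"
)

NUCLEIC_RESNAMES <- c(
  "A", "C", "G", "U", "I",
  "DA", "DC", "DG", "DT", "DU", "DI",
  "RA", "RC", "RG", "RU"
)

#' Read a single-structure PDB file
#'
#' Parses fixed-column `ATOM`/`HETATM` records into a structure model.
#' `HETATM` records are retained but flagged (`het = TRUE`). Insertion
#' codes are preserved as part of residue identity. If the file contains
#' `MODEL` records only the first model is returned, with a warning.
#' Alternate locations are resolved by keeping the highest-occupancy
#' variant of each atom (ties broken in favour of altloc `"A"`).
#'
#' @param path Path to a PDB file.
#' @return A `structure_model`: a list with element `atoms`, a data frame
#'   with one row per atom (columns `record`, `serial`, `name`, `altloc`,
#'   `resname`, `chain`, `resno`, `icode`, `x`, `y`, `z`, `occ`, `b`,
#'   `element`, `het`).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop_dccnet("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop_dccnet("empty PDB file: ", path)
  models <- split_models(lines)
  if (models$n_models > 1 || (models$n_models == 1 && models$explicit)) {
    if (models$n_models > 1) {
      warning("file contains ", models$n_models,
              " models; returning the first", call. = FALSE)
    }
  }
  atoms <- parse_atom_lines(lines[models$blocks[[1]]],
                            lineno = models$blocks[[1]])
  if (nrow(atoms) == 0) stop_dccnet("no ATOM/HETATM records in: ", path)
  atoms <- resolve_altloc(atoms)
  new_structure_model(atoms)
}

#' Read a multi-model PDB conformer ensemble
#'
#' Every frame must carry exactly the atoms of the first model, in the
#' same order; a mismatch is an error naming the offending model.
#'
#' @param path Path to a multi-model PDB file (frames delimited by
#'   `MODEL`/`ENDMDL`).
#' @return A `trajectory_ensemble`: list with `topology` (a
#'   `structure_model` from the first model) and `xyz`, an
#'   `F x A x 3` array of coordinates in Angstrom.
#' @export
read_ensemble <- function(path) {
  if (!file.exists(path)) stop_dccnet("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop_dccnet("empty PDB file: ", path)
  models <- split_models(lines)
  if (models$n_models < 1) stop_dccnet("no models found in: ", path)
  atoms1 <- parse_atom_lines(lines[models$blocks[[1]]],
                             lineno = models$blocks[[1]])
  if (nrow(atoms1) == 0) stop_dccnet("model 1 contains no atoms")
  atoms1 <- resolve_altloc(atoms1)
  n_atoms <- nrow(atoms1)
  n_frames <- models$n_models
  xyz <- array(NA_real_, dim = c(n_frames, n_atoms, 3))
  xyz[1, , ] <- as.matrix(atoms1[, c("x", "y", "z")])
  id1 <- atom_identity(atoms1)
  if (n_frames > 1) {
    for (f in 2:n_frames) {
      af <- parse_atom_lines(lines[models$blocks[[f]]],
                             lineno = models$blocks[[f]])
      af <- resolve_altloc(af)
      if (nrow(af) != n_atoms) {
        stop_dccnet("model ", f, ": ", nrow(af), " atoms, expected ", n_atoms)
      }
      if (!identical(atom_identity(af), id1)) {
        stop_dccnet("model ", f, ": atom order differs from model 1")
      }
      xyz[f, , ] <- as.matrix(af[, c("x", "y", "z")])
    }
  }
  new_trajectory_ensemble(new_structure_model(atoms1), xyz)
}

#' Select network nodes (one per polymer residue)
#'
#' Amino-acid residues are represented by their CA atom, nucleotide
#' residues by their P atom. Residues lacking the representative atom
#' are skipped with a warning (5'-terminal nucleotides routinely lack
#' P). Water, ligands and other non-polymer `HETATM` residues contribute
#' no nodes. Node order is stable: chain appearance order, then residue
#' number and insertion code.
#'
#' @param model A `structure_model`.
#' @return A `node_set`: data frame with columns `chain`, `resno`,
#'   `icode`, `resname`, `kind` (`"protein"` or `"nucleic"`) and
#'   `atom` (row index of the representative atom in `model$atoms`).
#' @export
select_nodes <- function(model) {
  atoms <- model$atoms
  resname <- toupper(trimws(atoms$resname))
  kind <- ifelse(resname %in% AMINO_RESNAMES, "protein",
                 ifelse(resname %in% NUCLEIC_RESNAMES, "nucleic", NA))
  rid <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "\r")
  keep <- !is.na(kind)
  first_of_res <- !duplicated(rid)
  res_rows <- which(keep & first_of_res)
  nodes <- list()
  skipped <- character()
  for (r in res_rows) {
    rows <- which(rid == rid[r])
    rep_name <- if (kind[r] == "protein") "CA" else "P"
    hit <- rows[trimws(atoms$name[rows]) == rep_name]
    if (length(hit) == 0) {
      skipped <- c(skipped, paste0(atoms$chain[r], ":", atoms$resno[r],
                                   trimws(atoms$icode[r])))
      next
    }
    nodes[[length(nodes) + 1]] <- data.frame(
      chain = atoms$chain[r], resno = atoms$resno[r], icode = atoms$icode[r],
      resname = resname[r], kind = kind[r], atom = hit[1],
      stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0) {
    warning("skipped ", length(skipped),
            " residue(s) lacking representative atom: ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ..." else "", call. = FALSE)
  }
  if (length(nodes) == 0) {
    warning("no polymer residues with representative atoms found",
            call. = FALSE)
    ns <- data.frame(chain = character(), resno = integer(),
                     icode = character(), resname = character(),
                     kind = character(), atom = integer(),
                     stringsAsFactors = FALSE)
  } else {
    ns <- do.call(rbind, nodes)
    # stable order: chain appearance order, then resno, then icode
    chain_rank <- match(ns$chain, unique(atoms$chain))
    ns <- ns[order(chain_rank, ns$resno, ns$icode), , drop = FALSE]
    rownames(ns) <- NULL
  }
  class(ns) <- c("node_set", class(ns))
  ns
}

#' Write a structure model as a PDB file
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  writeLines(c(format_atom_records(model$atoms), "END"), path)
  invisible(path)
}

#' Write a conformer ensemble as a multi-model PDB file
#'
#' @param ensemble A `trajectory_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  atoms <- ensemble$topology$atoms
  n_frames <- dim(ensemble$xyz)[1]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames)) {
    af <- atoms
    af$x <- ensemble$xyz[f, , 1]
    af$y <- ensemble$xyz[f, , 2]
    af$z <- ensemble$xyz[f, , 3]
    writeLines(c(sprintf("MODEL     %4d", f),
                 format_atom_records(af), "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write per-residue scalar values into the B-factor column
#'
#' Every atom of a keyed residue carries that residue's value, written
#' `%6.2f` and clamped to `[0, 999.99]` (with a warning when clamping
#' occurs). Atoms of unkeyed residues get `0.00`. Values containing
#' `NaN` are an error.
#'
#' @param model A `structure_model`.
#' @param values Named numeric vector; names are `"chain:resno"` (or
#'   `"chain:resno:icode"` for residues with insertion codes).
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_bfactors <- function(model, values, path) {
  if (any(is.nan(values))) stop_dccnet("NaN value in B-factor input")
  if (!is.numeric(values) || is.null(names(values))) {
    stop_dccnet("values must be a named numeric vector keyed by chain:resno")
  }
  atoms <- model$atoms
  key_plain <- paste0(atoms$chain, ":", atoms$resno)
  key_icode <- paste0(atoms$chain, ":", atoms$resno, ":", trimws(atoms$icode))
  b <- values[key_icode]
  b[is.na(b)] <- values[key_plain][is.na(b)]
  b[is.na(b)] <- 0
  if (any(b < 0 | b > 999.99)) {
    warning("B-factor value(s) clamped to [0, 999.99]", call. = FALSE)
    b <- pmin(pmax(b, 0), 999.99)
  }
  atoms$b <- unname(b)
  out <- model
  out$atoms <- atoms
  write_structure(out, path)
}

# Constructors and internal helpers -------------------------------------

new_structure_model <- function(atoms) {
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "structure_model")
}

new_trajectory_ensemble <- function(topology, xyz) {
  stopifnot(length(dim(xyz)) == 3, dim(xyz)[2] == nrow(topology$atoms),
            dim(xyz)[3] == 3)
  structure(list(topology = topology, xyz = xyz),
            class = "trajectory_ensemble")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat("structure_model:", nrow(a), "atoms,",
      length(unique(a$chain)), "chain(s),",
      sum(!duplicated(paste(a$chain, a$resno, a$icode))), "residues\n")
  invisible(x)
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat("trajectory_ensemble:", dim(x$xyz)[1], "frames x",
      dim(x$xyz)[2], "atoms\n")
  invisible(x)
}

atom_identity <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$icode, trimws(atoms$name))
}

# Split PDB lines into per-model blocks of line indices.
split_models <- function(lines) {
  rec <- substr(lines, 1, 6)
  is_model <- startsWith(rec, "MODEL")
  is_end <- startsWith(rec, "ENDMDL")
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_model)) {
    return(list(n_models = if (any(is_atom)) 1 else 0,
                blocks = list(which(is_atom)), explicit = FALSE))
  }
  starts <- which(is_model)
  ends <- which(is_end)
  if (length(ends) < length(starts)) {
    # tolerate a missing terminal ENDMDL
    ends <- c(ends, length(lines))
  }
  blocks <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    span <- seq(starts[k] + 1, ends[k] - 1)
    blocks[[k]] <- span[is_atom[span]]
  }
  list(n_models = length(starts), blocks = blocks, explicit = TRUE)
}

parse_atom_lines <- function(lines, lineno = seq_along(lines)) {
  n <- length(lines)
  if (n == 0) {
    return(data.frame(record = character(), serial = integer(),
                      name = character(), altloc = character(),
                      resname = character(), chain = character(),
                      resno = integer(), icode = character(),
                      x = double(), y = double(), z = double(),
                      occ = double(), b = double(), element = character(),
                      het = logical(), stringsAsFactors = FALSE))
  }
  field <- function(from, to) substr(lines, from, to)
  num_field <- function(from, to, what) {
    raw <- trimws(field(from, to))
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & raw != "")
    if (length(bad) > 0) {
      stop_dccnet("malformed ", what, " field at line ", lineno[bad[1]],
                  ": '", raw[bad[1]], "'")
    }
    val
  }
  x <- num_field(31, 38, "x")
  y <- num_field(39, 46, "y")
  z <- num_field(47, 54, "z")
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0) {
    stop_dccnet("missing coordinate at line ", lineno[bad[1]])
  }
  occ <- num_field(55, 60, "occupancy")
  occ[is.na(occ)] <- 1
  b <- num_field(61, 66, "b-factor")
  b[is.na(b)] <- 0
  serial <- suppressWarnings(as.integer(trimws(field(7, 11))))
  serial[is.na(serial)] <- seq_len(n)[is.na(serial)]
  resno <- suppressWarnings(as.integer(trimws(field(23, 26))))
  bad <- which(is.na(resno))
  if (length(bad) > 0) {
    stop_dccnet("malformed residue number at line ", lineno[bad[1]])
  }
  name <- trimws(field(13, 16))
  element <- trimws(field(77, 78))
  element[element == ""] <- guess_element(name[element == ""])
  data.frame(
    record = trimws(field(1, 6)), serial = serial, name = name,
    altloc = field(17, 17), resname = trimws(field(18, 20)),
    chain = field(22, 22), resno = resno, icode = field(27, 27),
    x = x, y = y, z = z, occ = occ, b = b,
    element = toupper(element), het = field(1, 6) == "HETATM",
    stringsAsFactors = FALSE)
}

# Element from atom name when columns 77-78 are blank: two-letter
# elements common in biomolecules, else the first alphabetic character.
guess_element <- function(name) {
  if (length(name) == 0) return(character())
  up <- toupper(name)
  two <- c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CA2", "SE")
  el <- substr(gsub("[^A-Z]", "", up), 1, 1)
  el[up %in% c("FE", "ZN", "MG", "MN", "SE")] <- up[up %in% two[1:5]]
  el
}

resolve_altloc <- function(atoms) {
  alt <- atoms$altloc
  if (all(alt == " " | alt == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$name, sep = "\r")
  # keep highest occupancy; ties prefer altloc 'A'
  pref <- order(key, -atoms$occ, atoms$altloc != "A", atoms$altloc)
  keep_first <- !duplicated(key[pref])
  kept <- sort(pref[keep_first])
  atoms[kept, , drop = FALSE]
}

format_atom_records <- function(atoms) {
  name4 <- vapply(atoms$name, function(nm) {
    if (nchar(nm) >= 4) substr(nm, 1, 4) else formatC(paste0(" ", nm),
                                                      width = -4)
  }, character(1))
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(atoms$het, "HETATM", "ATOM"),
          atoms$serial %% 100000, name4,
          substr(paste0(atoms$altloc, " "), 1, 1),
          formatC(atoms$resname, width = 3),
          substr(paste0(atoms$chain, " "), 1, 1),
          atoms$resno %% 10000,
          substr(paste0(atoms$icode, " "), 1, 1),
          atoms$x, atoms$y, atoms$z,
          pmin(pmax(atoms$occ, 0), 999.99),
          pmin(pmax(atoms$b, 0), 999.99),
          formatC(atoms$element, width = 2))
}
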