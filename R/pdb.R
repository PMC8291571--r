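WATER_RESNAMES <- c("HOH", "WAT", "TIP3")

# Canonical amino acids plus the common protonation-state variants used by
# biomolecular force fields.
STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HIE", "HID", "HIP", "ASH", "GLH", "LYN", "CYX", "CYM"
)

atom_columns <- function() {
  data.frame(
    serial = integer(), name = character(), element = character(),
    alt_loc = character(), res_name = character(), chain_id = character(),
    res_seq = integer(), ins_code = character(),
    x = double(), y = double(), z = double(), occupancy = double(),
    charge = double(), lj_sigma = double(), lj_epsilon = double(),
    mol_class = character(),
    stringsAsFactors = FALSE
  )
}

#' Construct a protofibril model from an atom table
#'
#' Low-level constructor used by [read_pdb()] and the fixture builders. The
#' atom table is validated (finite coordinates, non-empty element symbols,
#' occupancies in \[0, 1\]) and each residue is assigned a molecule class:
#' `"water"` for water residue names (HOH/WAT/TIP3), `"ligand"` for residue
#' names listed in `ligand_resnames`, `"protein"` for standard amino acids
#' that carry the backbone atoms N, CA and C, and `"other"` otherwise.
#'
#' @param atoms data frame with (at least) columns `serial`, `name`,
#'   `element`, `res_name`, `chain_id`, `res_seq`, `x`, `y`, `z`.
#'   Optional columns (`alt_loc`, `ins_code`, `occupancy`, `charge`,
#'   `lj_sigma`, `lj_epsilon`) are filled with defaults when absent.
#' @param ligand_resnames character vector of residue codes to classify as
#'   ligand.
#' @param source optional provenance string (file path).
#' @return an object of class `protofibril`: a list with the atom data frame
#'   (`$atoms`, including a per-atom `mol_class` column) and `$source`.
#' @export
protofibril <- function(atoms, ligand_resnames = character(), source = NA_character_) {
  stopifnot(is.data.frame(atoms))
  if (nrow(atoms) == 0L) stop("empty structure: no atoms")
  defaults <- list(alt_loc = "", ins_code = "", occupancy = 1,
                   charge = NA_real_, lj_sigma = NA_real_, lj_epsilon = NA_real_)
  for (nm in names(defaults)) {
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  }
  atoms$res_seq <- as.integer(atoms$res_seq)
  atoms$serial <- as.integer(atoms$serial)
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("non-finite coordinates in atom table")
  if (any(!nzchar(atoms$element))) stop("empty element symbol in atom table")
  occ <- atoms$occupancy
  if (any(!is.na(occ) & (occ < 0 | occ > 1))) stop("occupancy outside [0, 1]")

  atoms$mol_class <- classify_residues(atoms, ligand_resnames)
  obj <- list(atoms = atoms, source = source,
              ligand_resnames = as.character(ligand_resnames))
  class(obj) <- "protofibril"
  obj
}

classify_residues <- function(atoms, ligand_resnames) {
  key <- residue_key(atoms)
  cls <- character(nrow(atoms))
  for (k in unique(key)) {
    idx <- which(key == k)
    rn <- atoms$res_name[idx[1]]
    cls[idx] <-
      if (rn %in% WATER_RESNAMES) "water"
      else if (rn %in% ligand_resnames) "ligand"
      else if (rn %in% STANDARD_AA &&
               all(c("N", "CA", "C") %in% atoms$name[idx])) "protein"
      else "other"
  }
  cls
}

residue_key <- function(atoms) {
  paste(atoms$chain_id, atoms$res_seq, atoms$ins_code, sep = "\r")
}

#' Residue table of a protofibril model
#'
#' One row per residue, in order of first appearance, with the residue
#' identity and molecule class.
#'
#' @param model a `protofibril` object.
#' @return data frame with columns `chain_id`, `res_seq`, `ins_code`,
#'   `res_name`, `mol_class`, `n_atoms`.
#' @export
residue_table <- function(model) {
  a <- model$atoms
  key <- residue_key(a)
  first <- !duplicated(key)
  data.frame(
    chain_id = a$chain_id[first], res_seq = a$res_seq[first],
    ins_code = a$ins_code[first], res_name = a$res_name[first],
    mol_class = a$mol_class[first],
    n_atoms = as.integer(table(factor(key, levels = key[first]))),
    stringsAsFactors = FALSE
  )
}

#' @export
print.protofibril <- function(x, ...) {
  rt <- residue_table(x)
  cat("protofibril model:", nrow(x$atoms), "atoms,", nrow(rt), "residues,",
      length(unique(x$atoms$chain_id)), "chains\n")
  tab <- table(rt$mol_class)
  cat("  residues by class:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (!is.na(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' Atoms of a model by molecule class
#'
#' @param model a `protofibril` object.
#' @param class_ molecule class to select (`"protein"`, `"ligand"`,
#'   `"water"`, `"other"`).
#' @return the matching rows of the atom data frame.
#' @export
model_atoms <- function(model, class_ = NULL) {
  a <- model$atoms
  if (is.null(class_)) a else a[a$mol_class %in% class_, , drop = FALSE]
}

#' Read a PDB file into a protofibril model
#'
#' Parses fixed-column `ATOM`/`HETATM` records. Only the first model of a
#' multi-model file is kept (a warning is issued for the rest). Alternate
#' locations are resolved by keeping, for each (chain, residue, atom name),
#' the record with the highest occupancy; ties keep the first encountered.
#' Residues are classified as water (HOH/WAT/TIP3), ligand (codes in
#' `ligand_resnames`), protein (standard amino acid with N/CA/C backbone),
#' or other.
#'
#' @param path path to a PDB file.
#' @param ligand_resnames character vector of ligand residue codes.
#' @return a [protofibril()] object.
#' @export
read_pdb <- function(path, ligand_resnames = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")

  # keep the first MODEL only
  endmdl <- which(trimws(rec) == "ENDMDL")
  if (length(endmdl)) {
    if (any(is_atom & seq_along(lines) > endmdl[1]))
      warning("multi-model file: keeping first model only")
    is_atom <- is_atom & seq_along(lines) < endmdl[1]
  }
  idx <- which(is_atom)
  if (length(idx) == 0L) stop("empty structure: no ATOM/HETATM records in ", path)

  ln <- lines[idx]
  num <- function(s, what, required = TRUE) {
    s <- trimws(s)
    v <- suppressWarnings(as.numeric(s))
    bad <- is.na(v) & (required | nzchar(s))
    if (any(bad)) {
      stop("malformed ATOM record (bad ", what, ") at line ",
           idx[which(bad)[1]], " of ", path)
    }
    v
  }
  name <- trimws(substr(ln, 13, 16))
  element <- trimws(substr(ln, 77, 78))
  element <- ifelse(nzchar(element), element, guess_element(name))
  atoms <- data.frame(
    serial = as.integer(num(substr(ln, 7, 11), "serial")),
    name = name,
    element = element,
    alt_loc = trimws(substr(ln, 17, 17)),
    res_name = trimws(substr(ln, 18, 20)),
    chain_id = substr(ln, 22, 22),
    res_seq = as.integer(num(substr(ln, 23, 26), "residue number")),
    ins_code = trimws(substr(ln, 27, 27)),
    x = num(substr(ln, 31, 38), "x coordinate"),
    y = num(substr(ln, 39, 46), "y coordinate"),
    z = num(substr(ln, 47, 54), "z coordinate"),
    occupancy = {
      o <- num(substr(ln, 55, 60), "occupancy", required = FALSE)
      ifelse(is.na(o), 1, o)
    },
    stringsAsFactors = FALSE
  )
  atoms <- resolve_alt_locs(atoms)
  protofibril(atoms, ligand_resnames = ligand_resnames, source = path)
}

# element from the atom name when columns 77-78 are blank: strip digits and
# primes; names packed into column 13 ("1HB2") start with a digit for H
guess_element <- function(name) {
  s <- gsub("[0-9']", "", name)
  el <- ifelse(nchar(s) >= 2 & s %in% c("CL", "BR", "NA", "MG", "ZN", "FE",
                                        "MN", "SE", "CA"),
               s, substr(s, 1, 1))
  # two-letter ambiguity (CA calcium vs C-alpha) resolved in favour of carbon
  # for names that look like standard protein atoms
  el[name %in% c("CA", "CB", "CG", "CD", "CE", "CZ")] <- "C"
  el
}

resolve_alt_locs <- function(atoms) {
  if (all(!nzchar(atoms$alt_loc))) return(atoms)
  key <- paste(residue_key(atoms), atoms$name, sep = "\r")
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[duplicated(key)])) {
    g <- which(key == k)
    best <- g[which.max(atoms$occupancy[g])]  # ties: first occurrence
    keep[setdiff(g, best)] <- FALSE
  }
  atoms <- atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  atoms
}

#' Write a protofibril model as a PDB file
#'
#' Fixed-column `ATOM` records (HETATM for non-protein residues), `TER`
#' after each chain, `END` last. Coordinates are written at the standard
#' 0.001 Angstrom precision.
#'
#' @param model a `protofibril` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  fmt_name <- function(name, element) {
    # column alignment rule: 1-char elements with short names start in col 14
    ifelse(nchar(name) >= 4 | nchar(element) >= 2,
           formatC(name, width = -4), paste0(" ", formatC(name, width = -3)))
  }
  rec <- ifelse(a$mol_class == "protein", "ATOM  ", "HETATM")
  out <- sprintf("%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 rec, a$serial %% 100000L, fmt_name(a$name, a$element),
                 substr(a$alt_loc, 1, 1), a$res_name, a$chain_id,
                 a$res_seq %% 10000L, substr(a$ins_code, 1, 1),
                 a$x, a$y, a$z, a$occupancy, 0, a$element)
  ter_after <- which(a$chain_id != c(a$chain_id[-1], NA_character_))
  ter_after <- c(ter_after, nrow(a))
  lines <- character(0)
  start <- 1L
  for (e in unique(ter_after)) {
    lines <- c(lines, out[start:e], "TER")
    start <- e + 1L
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Coordinates of an atom table as a matrix
#'
#' @param atoms atom data frame (rows of `model$atoms`).
#' @return numeric N x 3 matrix.
#' @export
atom_coords <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}
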