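# ---- deterministic synthetic structures ------------------------------------

# ideal backbone geometry (Angstrom / degrees) used by the generators
BB_N_CA <- 1.46
BB_CA_C <- 1.52
BB_C_N <- 1.33
BB_C_O <- 1.23
ANG_N_CA_C <- 110
ANG_CA_C_N <- 116
ANG_C_N_CA <- 122

#' Specification for a synthetic fixture structure
#'
#' Describes a deterministic toy complex: an ideal-geometry extended
#' peptide (optionally replicated into a stack of chains by a screw
#' operator, emulating the filament stacking of an amyloid protofibril
#' with its ~4.8 Angstrom rise), a small rigid probe ligand, and water
#' molecules on a seeded jittered grid.
#'
#' @param sequence character vector of residue codes (3-letter).
#' @param n_chains number of stacked chains.
#' @param chain_rise rise per chain along z, Angstrom.
#' @param chain_twist twist per chain about z, degrees.
#' @param ligand `"none"`, `"two_atom_probe"` or `"ring_probe"`.
#' @param ligand_offset 3-vector: ligand centre relative to the peptide
#'   centroid, Angstrom.
#' @param n_waters number of water molecules.
#' @param seed integer seed controlling water placement.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(sequence = c("GLY", "GLY", "GLY"), n_chains = 1,
                         chain_rise = 4.8, chain_twist = 0,
                         ligand = c("none", "two_atom_probe", "ring_probe"),
                         ligand_offset = c(0, 6, 0), n_waters = 0, seed = 1) {
  ligand <- match.arg(ligand)
  stopifnot(length(sequence) >= 1, n_chains >= 1, n_waters >= 0,
            length(ligand_offset) == 3)
  if (n_chains > 1 && chain_rise <= 0)
    stop("chain_rise must be positive for multi-chain fixtures")
  unknown <- setdiff(sequence, names(FORMAL_CHARGES))
  if (length(unknown))
    stop("unsupported residue code(s): ", paste(unknown, collapse = ", "))
  structure(list(sequence = sequence, n_chains = n_chains,
                 chain_rise = chain_rise, chain_twist = chain_twist,
                 ligand = ligand, ligand_offset = as.numeric(ligand_offset),
                 n_waters = as.integer(n_waters), seed = as.integer(seed)),
            class = "fixture_spec")
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# extended backbone laid out in the z = 0 plane: atoms placed sequentially
# with exact bond lengths and alternating in-plane bond angles, so the
# C(i)-N(i+1) distance is 1.33 A by construction
single_chain_atoms <- function(sequence, chain_id) {
  n <- length(sequence)
  bonds <- rep(c(BB_N_CA, BB_CA_C, BB_C_N), n)[seq_len(3 * n - 1)]
  angles <- rep(c(ANG_N_CA_C, ANG_CA_C_N, ANG_C_N_CA), n)[seq_len(max(3 * n - 2, 0))]
  pos <- matrix(0, 3 * n, 3)
  dir_angle <- 0
  pos[1, ] <- c(0, 0, 0)
  s <- 1
  for (k in seq_len(3 * n - 1)) {
    if (k >= 2) {
      dir_angle <- dir_angle + s * (180 - angles[k - 1])
      s <- -s
    }
    th <- dir_angle * pi / 180
    pos[k + 1, ] <- pos[k, ] + bonds[k] * c(cos(th), sin(th), 0)
  }
  names_bb <- rep(c("N", "CA", "C"), n)
  res_idx <- rep(seq_len(n), each = 3)

  # carbonyl O in-plane off each C, bisecting away from CA and next N
  o_pos <- t(vapply(seq_len(n), function(i) {
    c_i <- pos[3 * i - 0, ]  # row of C of residue i
    ca_i <- pos[3 * i - 1, ]
    ref <- if (i < n) pos[3 * i + 1, ] else ca_i + (c_i - ca_i) * 2  # virtual N
    d <- -(unitv(ca_i - c_i) + unitv(ref - c_i))
    if (sqrt(sum(d^2)) < 1e-9) d <- c(0, 0, 1)
    c_i + BB_C_O * unitv(d)
  }, numeric(3)))

  atoms <- data.frame(
    serial = NA_integer_,
    name = c(names_bb, rep("O", n)),
    element = c(substr(names_bb, 1, 1), rep("O", n)),
    alt_loc = "", res_name = c(sequence[res_idx], sequence),
    chain_id = chain_id, res_seq = c(res_idx, seq_len(n)), ins_code = "",
    x = c(pos[, 1], o_pos[, 1]), y = c(pos[, 2], o_pos[, 2]),
    z = c(pos[, 3], o_pos[, 3]), occupancy = 1,
    stringsAsFactors = FALSE
  )
  atoms <- atoms[order(atoms$res_seq, match(atoms$name, c("N", "CA", "C", "O"))), ]
  rownames(atoms) <- NULL
  atoms
}

#' Build an ideal-geometry peptide (optionally a stacked multi-chain fibril)
#'
#' Backbone-only (N, CA, C, O) extended peptide with exact standard bond
#' lengths (N-CA 1.46, CA-C 1.52, C-N 1.33, C-O 1.23 Angstrom); chain k of
#' a multi-chain fixture is the first chain rotated by
#' `(k-1) * chain_twist` about z and raised by `(k-1) * chain_rise` along
#' z. Output is fully deterministic for a given spec, and all atoms are
#' parameterized (charge 0, built-in element Lennard-Jones values).
#'
#' @param spec a [fixture_spec()].
#' @return a `protofibril`.
#' @export
build_peptide <- function(spec) {
  chain_ids <- c(LETTERS, letters)[seq_len(spec$n_chains)]
  base <- single_chain_atoms(spec$sequence, chain_ids[1])
  chains <- lapply(seq_len(spec$n_chains), function(k) {
    a <- base
    a$chain_id <- chain_ids[k]
    xyz <- atom_coords(a) %*% t(rot_z(spec$chain_twist * (k - 1)))
    xyz[, 3] <- xyz[, 3] + spec$chain_rise * (k - 1)
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    a
  })
  atoms <- do.call(rbind, chains)
  atoms$serial <- seq_len(nrow(atoms))
  assign_parameters(protofibril(atoms, source = "synthetic fixture"))
}

ligand_atoms <- function(kind, centre, chain_id = "L") {
  xyz <- switch(kind,
    two_atom_probe = rbind(c(-0.7, 0, 0), c(0.7, 0, 0)),
    ring_probe = {
      th <- (0:5) * pi / 3
      cbind(1.39 * cos(th), 1.39 * sin(th), 0)
    },
    stop("unknown ligand kind: ", kind))
  xyz <- sweep(xyz, 2, centre, "+")
  n <- nrow(xyz)
  data.frame(serial = NA_integer_, name = paste0("C", seq_len(n)),
             element = "C", alt_loc = "", res_name = "LIG",
             chain_id = chain_id, res_seq = 1L, ins_code = "",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occupancy = 1,
             stringsAsFactors = FALSE)
}

water_atoms <- function(o_pos, res_seq, chain_id = "W") {
  # rigid TIP3P-like geometry: O-H 0.9572 A, H-O-H 104.52 deg, fixed
  # orientation (determinism over realism)
  hoh <- 104.52 * pi / 180
  h1 <- o_pos + 0.9572 * c(1, 0, 0)
  h2 <- o_pos + 0.9572 * c(cos(hoh), sin(hoh), 0)
  data.frame(serial = NA_integer_, name = c("O", "H1", "H2"),
             element = c("O", "H", "H"), alt_loc = "", res_name = "HOH",
             chain_id = chain_id, res_seq = res_seq, ins_code = "",
             x = c(o_pos[1], h1[1], h2[1]), y = c(o_pos[2], h1[2], h2[2]),
             z = c(o_pos[3], h1[3], h2[3]), occupancy = 1,
             stringsAsFactors = FALSE)
}

#' Build a synthetic protein-ligand(-water) complex
#'
#' The peptide of [build_peptide()], a rigid probe ligand placed at
#' `spec$ligand_offset` from the peptide centroid, and `spec$n_waters`
#' waters on a deterministic jittered grid around the solutes (seeded by
#' `spec$seed`; every water oxygen keeps at least 2.5 Angstrom from all
#' solute and previously placed water atoms). All atoms are parameterized
#' from the built-in tables (protein and ligand charges 0, waters
#' TIP3P-like); tests plant charges by editing the returned atom table.
#'
#' @param spec a [fixture_spec()] with `ligand != "none"`.
#' @param water_positions optional N x 3 matrix of water oxygen positions
#'   overriding grid placement (N >= `spec$n_waters` rows are not required;
#'   exactly `n_waters` rows are).
#' @return a `protofibril` with protein, ligand and water molecule classes.
#' @export
build_complex <- function(spec, water_positions = NULL) {
  if (spec$ligand == "none") stop("build_complex needs a ligand; use build_peptide")
  pep <- build_peptide(spec)
  centre <- colMeans(atom_coords(pep$atoms))
  lig <- ligand_atoms(spec$ligand, centre + spec$ligand_offset)
  atoms <- rbind(pep$atoms[, names(lig)], lig)

  if (spec$n_waters > 0L) {
    if (is.null(water_positions)) {
      water_positions <- place_waters_grid(atom_coords(atoms), spec$n_waters,
                                           spec$seed)
    } else {
      water_positions <- as.matrix(water_positions)
      if (nrow(water_positions) != spec$n_waters)
        stop("water_positions must have exactly n_waters rows")
    }
    wat <- do.call(rbind, lapply(seq_len(spec$n_waters), function(i)
      water_atoms(water_positions[i, ], res_seq = i)))
    atoms <- rbind(atoms, wat)
  }
  atoms$serial <- seq_len(nrow(atoms))
  assign_parameters(protofibril(atoms, ligand_resnames = "LIG",
                                source = "synthetic fixture"))
}

place_waters_grid <- function(solute_xyz, n_waters, seed) {
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(state)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", state, envir = globalenv())
  })
  set.seed(seed)
  lo <- apply(solute_xyz, 2, min); hi <- apply(solute_xyz, 2, max)
  placed <- matrix(0, 0, 3)
  for (pad in c(4, 7, 10)) {           # bounded expansion attempts
    grid <- expand.grid(x = seq(lo[1] - pad, hi[1] + pad, by = 3),
                        y = seq(lo[2] - pad, hi[2] + pad, by = 3),
                        z = seq(lo[3] - pad, hi[3] + pad, by = 3))
    pts <- as.matrix(grid) + matrix(stats::runif(3 * nrow(grid), -0.5, 0.5),
                                    ncol = 3)
    for (i in seq_len(nrow(pts))) {
      p <- pts[i, ]
      d_sol <- min(sqrt(rowSums(sweep(solute_xyz, 2, p)^2)))
      d_wat <- if (nrow(placed)) min(sqrt(rowSums(sweep(placed, 2, p)^2))) else Inf
      if (d_sol >= 2.5 && d_wat >= 2.5) {
        placed <- rbind(placed, p)
        if (nrow(placed) == n_waters) return(placed)
      }
    }
  }
  stop("could not place ", n_waters, " waters after bounded attempts")
}
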