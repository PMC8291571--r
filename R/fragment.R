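# ---- residue formal charges (pH 7, side chains only) -----------------------

FORMAL_CHARGES <- c(
  ALA = 0, ARG = 1, ASN = 0, ASP = -1, CYS = 0, GLN = 0, GLU = -1, GLY = 0,
  HIS = 0, ILE = 0, LEU = 0, LYS = 1, MET = 0, PHE = 0, PRO = 0, SER = 0,
  THR = 0, TRP = 0, TYR = 0, VAL = 0,
  HIE = 0, HID = 0, HIP = 1, ASH = 0, GLH = 0, LYN = 0, CYX = 0, CYM = -1
)

# link-atom cap bond lengths (Angstrom)
CAP_H_FROM_C <- 1.09   # H replacing the N across the cut, bonded to C
CAP_H_FROM_N <- 1.01   # H replacing the C across the cut, bonded to N
PEPTIDE_BOND_CUTOFF <- 1.8

residue_formal_charge <- function(res_name, his_charge = 0) {
  ch <- FORMAL_CHARGES[res_name]
  ch[res_name %in% c("HIS", "HIE", "HID")] <- his_charge
  if (anyNA(ch)) {
    stop("no formal-charge rule for residue(s): ",
         paste(unique(res_name[is.na(ch)]), collapse = ", "),
         " (supply charge_rules to override)")
  }
  unname(ch)
}

# ---- peptide-bond detection ------------------------------------------------

#' Detect peptide bonds along a protein chain
#'
#' For each pair of consecutive protein residues in a chain, the bond
#' `C(i)-N(i+1)` is reported when the two atoms lie within the detection
#' cutoff (default 1.8 Angstrom, comfortably covering the 1.32-1.35
#' Angstrom range of real peptide bonds). Pairs beyond the cutoff are
#' treated as chain breaks and collected in the `"breaks"` attribute.
#'
#' @param model a `protofibril`.
#' @param chain_id chain identifier.
#' @param cutoff detection cutoff in Angstrom.
#' @return data frame with one row per bond: `res_seq_i`, `res_seq_j`,
#'   `length` (Angstrom), plus attribute `breaks` (data frame of skipped
#'   pairs with their C-N distances).
#' @export
find_peptide_bonds <- function(model, chain_id, cutoff = PEPTIDE_BOND_CUTOFF) {
  res <- chain_protein_residues(model, chain_id)
  n <- nrow(res)
  bonds <- data.frame(res_seq_i = integer(), res_seq_j = integer(), length = double())
  breaks <- bonds
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      ci <- backbone_atom(model, chain_id, res[i, ], "C")
      nj <- backbone_atom(model, chain_id, res[i + 1L, ], "N")
      d <- sqrt(sum((ci - nj)^2))
      row <- data.frame(res_seq_i = res$res_seq[i], res_seq_j = res$res_seq[i + 1L],
                        length = d)
      if (d <= cutoff) bonds <- rbind(bonds, row) else breaks <- rbind(breaks, row)
    }
  }
  if (nrow(breaks))
    warning(nrow(breaks), " chain break(s) in chain ", chain_id,
            " (C-N distance above ", cutoff, " A)")
  attr(bonds, "breaks") <- breaks
  bonds
}

chain_protein_residues <- function(model, chain_id) {
  rt <- residue_table(model)
  res <- rt[rt$chain_id == chain_id & rt$mol_class == "protein", , drop = FALSE]
  if (nrow(res) == 0L) {
    if (!chain_id %in% rt$chain_id) stop("no such chain: ", chain_id)
    stop("chain ", chain_id, " contains no protein residues")
  }
  rownames(res) <- NULL
  res
}

residue_atoms <- function(model, chain_id, res_row) {
  a <- model$atoms
  a[a$chain_id == chain_id & a$res_seq == res_row$res_seq &
      a$ins_code == res_row$ins_code, , drop = FALSE]
}

backbone_atom <- function(model, chain_id, res_row, name, required = TRUE) {
  a <- residue_atoms(model, chain_id, res_row)
  hit <- a[a$name == name, , drop = FALSE]
  if (nrow(hit) == 0L) {
    if (!required) return(NULL)
    stop("residue ", res_row$res_name, " ", chain_id, ":", res_row$res_seq,
         " is missing backbone atom ", name)
  }
  c(hit$x[1], hit$y[1], hit$z[1])
}

# ---- cap construction ------------------------------------------------------

unitv <- function(v) v / sqrt(sum(v^2))

cap_atom_row <- function(template_row, name, element, xyz, bond_label,
                         charge = 0, lj_sigma = 0, lj_epsilon = 0) {
  r <- template_row
  r$name <- name; r$element <- element
  r$x <- xyz[1]; r$y <- xyz[2]; r$z <- xyz[3]
  r$alt_loc <- ""; r$occupancy <- 1
  r$charge <- charge; r$lj_sigma <- lj_sigma; r$lj_epsilon <- lj_epsilon
  r$cap_bond <- bond_label
  r
}

# three tetrahedral H around a methyl carbon whose remaining bond points to
# `anchor`; the azimuthal reference frame is fixed by the lab axis least
# aligned with the bond, so placement is deterministic
methyl_hydrogens <- function(cm, anchor, bond = CAP_H_FROM_C) {
  a <- unitv(anchor - cm)                    # direction of the C-X bond
  ref <- diag(3)[, which.min(abs(a))]
  e1 <- unitv(ref - sum(ref * a) * a)
  e2 <- c(a[2] * e1[3] - a[3] * e1[2],
          a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  cost <- -1 / 3                              # cos(109.471 deg)
  sint <- sqrt(1 - cost^2)
  phis <- c(0, 2 * pi / 3, 4 * pi / 3)
  t(vapply(phis, function(phi) {
    d <- cost * a + sint * (cos(phi) * e1 + sin(phi) * e2)
    cm + bond * d
  }, numeric(3)))
}

# ---- fragmentation ---------------------------------------------------------

new_fragment <- function(fragment_id, core, caps, net_charge, source_residues) {
  stopifnot(nrow(core) > 0L)
  structure(list(fragment_id = fragment_id, core = core, caps = caps,
                 net_charge = as.integer(net_charge), multiplicity = 1L,
                 source_residues = source_residues),
            class = "fragment")
}

#' @export
print.fragment <- function(x, ...) {
  cat(sprintf("fragment %s: %d core + %d cap atoms, charge %+d, multiplicity %d\n",
              x$fragment_id, nrow(x$core), nrow(x$caps), x$net_charge,
              x$multiplicity))
  invisible(x)
}

#' All atoms of a fragment (core plus caps)
#'
#' @param fragment a `fragment`.
#' @param zero_cap_params if `TRUE`, cap atoms are returned with zero charge
#'   and Lennard-Jones parameters (a testing switch that makes fragment sums
#'   exactly additive for pairwise backends).
#' @return atom data frame.
#' @export
fragment_atoms <- function(fragment, zero_cap_params = FALSE) {
  core <- fragment$core
  caps <- fragment$caps
  core$cap_bond <- NULL
  caps$cap_bond <- NULL
  if (nrow(caps) && zero_cap_params) {
    caps$charge <- 0; caps$lj_sigma <- 0; caps$lj_epsilon <- 0
  }
  rbind(core, caps)
}

#' Cleave a protein chain into capped fragments
#'
#' Implements peptide-bond fragmentation: the chain is cut along every
#' detected peptide bond and each piece is closed with synthetic caps so
#' that it is a chemically sensible closed-shell molecule.
#'
#' Capping schemes:
#' \describe{
#'   \item{hydrogen}{the atom across each cut bond is replaced by a link
#'     hydrogen placed along the original bond vector, 1.09 Angstrom from
#'     the carbonyl C (replacing N) and 1.01 Angstrom from the amide N
#'     (replacing C).}
#'   \item{methylamide}{the piece N-terminal of a cut receives an
#'     N-methylamide (NH-CH3) cap and the C-terminal piece an acetyl
#'     (CO-CH3) cap. Cap heavy atoms reuse the positions of the original
#'     neighbouring backbone atoms (N/CA across the bond for the
#'     N-methylamide; C/O/CA for the acetyl), so the fragment geometry stays
#'     faithful to the input snapshot; only atoms that did not exist (amide
#'     H when absent, methyl hydrogens) are synthesised, deterministically.}
#' }
#'
#' Fragment net charges are the sum of standard pH-7 side-chain formal
#' charges of the core residues (ASP/GLU -1, LYS/ARG +1, HIS neutral by
#' default); all fragments are singlets.
#'
#' With `order = "dipeptide"` overlapping two-residue windows are produced,
#' one per detected peptide bond (a window never spans a chain break), with
#' the shared bond left intact and caps at the outer cut ends.
#'
#' @param model a `protofibril`.
#' @param chain_id chain to fragment.
#' @param scheme `"hydrogen"` or `"methylamide"`.
#' @param order `"monopeptide"` (one residue per fragment) or `"dipeptide"`.
#' @param his_charge formal charge to assign HIS/HIE/HID side chains.
#' @param charge_rules optional named numeric vector of per-residue formal
#'   charges overriding or extending the built-in table.
#' @param cap_params if `TRUE` (default) cap atoms receive Lennard-Jones
#'   parameters from the built-in element table (charge 0); if `FALSE` caps
#'   carry zero parameters.
#' @return list of `fragment` objects.
#' @export
fragment_chain <- function(model, chain_id,
                           scheme = c("hydrogen", "methylamide"),
                           order = c("monopeptide", "dipeptide"),
                           his_charge = 0, charge_rules = NULL,
                           cap_params = TRUE) {
  scheme <- match.arg(scheme)
  order <- match.arg(order)
  res <- chain_protein_residues(model, chain_id)
  n <- nrow(res)
  if (order == "dipeptide" && n < 2L)
    stop("dipeptide fragmentation needs at least 2 residues in chain ", chain_id)

  charges <- FORMAL_CHARGES
  charges[names(charges) %in% c("HIS", "HIE", "HID")] <- his_charge
  if (!is.null(charge_rules)) charges[names(charge_rules)] <- charge_rules
  res_charge <- charges[res$res_name]
  if (anyNA(res_charge))
    stop("no formal-charge rule for residue(s): ",
         paste(unique(res$res_name[is.na(res_charge)]), collapse = ", "))

  bonds <- suppressWarnings(find_peptide_bonds(model, chain_id))
  bonded <- logical(max(n - 1L, 0L))  # bonded[i]: residue i bonded to i+1
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      bonded[i] <- any(bonds$res_seq_i == res$res_seq[i] &
                         bonds$res_seq_j == res$res_seq[i + 1L])
    }
  }

  atoms_by_res <- lapply(seq_len(n), function(i) residue_atoms(model, chain_id, res[i, ]))

  if (order == "monopeptide") {
    windows <- lapply(seq_len(n), function(i) i)
  } else {
    windows <- lapply(which(bonded), function(i) c(i, i + 1L))
    if (length(windows) == 0L)
      stop("no intact peptide bonds in chain ", chain_id,
           ": dipeptide windows undefined")
  }

  lapply(windows, function(w) {
    core <- do.call(rbind, atoms_by_res[w])
    core$cap_bond <- NA_character_
    caps <- core[0, , drop = FALSE]
    first <- w[1]; last <- w[length(w)]
    # cut on the N-terminal side of the window: bond C(first-1) - N(first)
    if (first > 1L && bonded[first - 1L]) {
      caps <- rbind(caps, build_n_side_cap(model, chain_id, res, first, scheme))
    }
    # cut on the C-terminal side: bond C(last) - N(last+1)
    if (last < n && bonded[last]) {
      caps <- rbind(caps, build_c_side_cap(model, chain_id, res, last, scheme))
    }
    if (isTRUE(cap_params) && nrow(caps)) {
      lj <- element_lj_defaults(caps$element)
      caps$lj_sigma <- lj$lj_sigma; caps$lj_epsilon <- lj$lj_epsilon
    }
    rng <- if (length(w) == 1L) res$res_seq[w] else
      paste0(res$res_seq[first], "-", res$res_seq[last])
    frag <- new_fragment(
      fragment_id = paste0(chain_id, ":", rng),
      core = core, caps = caps,
      net_charge = sum(res_charge[w]),
      source_residues = data.frame(chain_id = chain_id,
                                   res_seq = res$res_seq[w],
                                   res_name = res$res_name[w],
                                   stringsAsFactors = FALSE)
    )
    validate_fragment_caps(frag, scheme)
    frag
  })
}

# cap closing the cut C(i-1)-N(i), attached to the window that starts at
# residue i: acetyl (methylamide scheme) or link H bonded to N(i)
build_n_side_cap <- function(model, chain_id, res, i, scheme) {
  bond_label <- sprintf("C(%s:%d)-N(%s:%d)", chain_id, res$res_seq[i - 1L],
                        chain_id, res$res_seq[i])
  n_i <- backbone_atom(model, chain_id, res[i, ], "N")
  c_prev <- backbone_atom(model, chain_id, res[i - 1L, ], "C")
  tmpl <- residue_atoms(model, chain_id, res[i, ])[1, , drop = FALSE]
  tmpl$cap_bond <- NA_character_
  if (scheme == "hydrogen") {
    h <- n_i + CAP_H_FROM_N * unitv(c_prev - n_i)
    return(cap_atom_row(tmpl, "HCP", "H", h, bond_label))
  }
  # acetyl: C and O at the original carbonyl positions, methyl C at the old
  # CA, methyl H synthesised
  o_prev <- backbone_atom(model, chain_id, res[i - 1L, ], "O", required = FALSE)
  ca_prev <- backbone_atom(model, chain_id, res[i - 1L, ], "CA")
  if (is.null(o_prev)) {
    d <- -unitv(unitv(n_i - c_prev) + unitv(ca_prev - c_prev))
    o_prev <- c_prev + 1.23 * d
  }
  hs <- methyl_hydrogens(ca_prev, c_prev)
  rbind(
    cap_atom_row(tmpl, "CAC", "C", c_prev, bond_label),
    cap_atom_row(tmpl, "OAC", "O", o_prev, bond_label),
    cap_atom_row(tmpl, "CME", "C", ca_prev, bond_label),
    cap_atom_row(tmpl, "HM1", "H", hs[1, ], bond_label),
    cap_atom_row(tmpl, "HM2", "H", hs[2, ], bond_label),
    cap_atom_row(tmpl, "HM3", "H", hs[3, ], bond_label)
  )
}

# cap closing the cut C(i)-N(i+1), attached to the window that ends at
# residue i: N-methylamide or link H bonded to C(i)
build_c_side_cap <- function(model, chain_id, res, i, scheme) {
  bond_label <- sprintf("C(%s:%d)-N(%s:%d)", chain_id, res$res_seq[i],
                        chain_id, res$res_seq[i + 1L])
  c_i <- backbone_atom(model, chain_id, res[i, ], "C")
  n_next <- backbone_atom(model, chain_id, res[i + 1L, ], "N")
  tmpl <- residue_atoms(model, chain_id, res[i, ])[1, , drop = FALSE]
  tmpl$cap_bond <- NA_character_
  if (scheme == "hydrogen") {
    h <- c_i + CAP_H_FROM_C * unitv(n_next - c_i)
    return(cap_atom_row(tmpl, "HCP", "H", h, bond_label))
  }
  ca_next <- backbone_atom(model, chain_id, res[i + 1L, ], "CA")
  # amide H: reuse the original backbone amide hydrogen when present
  next_atoms <- residue_atoms(model, chain_id, res[i + 1L, ])
  h_row <- next_atoms[next_atoms$name %in% c("H", "HN", "H1") &
                        next_atoms$element == "H", , drop = FALSE]
  hn <- if (nrow(h_row)) c(h_row$x[1], h_row$y[1], h_row$z[1]) else
    n_next + CAP_H_FROM_N * -unitv(unitv(c_i - n_next) + unitv(ca_next - n_next))
  hs <- methyl_hydrogens(ca_next, n_next)
  rbind(
    cap_atom_row(tmpl, "NMA", "N", n_next, bond_label),
    cap_atom_row(tmpl, "HNM", "H", hn, bond_label),
    cap_atom_row(tmpl, "CME", "C", ca_next, bond_label),
    cap_atom_row(tmpl, "HM1", "H", hs[1, ], bond_label),
    cap_atom_row(tmpl, "HM2", "H", hs[2, ], bond_label),
    cap_atom_row(tmpl, "HM3", "H", hs[3, ], bond_label)
  )
}

validate_fragment_caps <- function(frag, scheme) {
  if (nrow(frag$caps) == 0L) return(invisible(frag))
  cap_xyz <- atom_coords(frag$caps)
  core <- frag$core
  heavy_xyz <- atom_coords(core[core$element != "H", , drop = FALSE])
  all_xyz <- rbind(atom_coords(core), cap_xyz)
  n_core <- nrow(core)
  for (i in seq_len(nrow(cap_xyz))) {
    d_heavy <- sqrt(rowSums(sweep(heavy_xyz, 2, cap_xyz[i, ])^2))
    d_all <- sqrt(rowSums(sweep(all_xyz, 2, cap_xyz[i, ])^2))
    d_all <- d_all[-(n_core + i)]  # exclude the cap atom itself
    if (scheme == "hydrogen") {
      # a link H is bonded to exactly one core heavy atom
      if (sum(d_heavy <= 2.0) != 1L)
        stop("cap atom ", frag$caps$name[i], " of ", frag$fragment_id,
             " is not within 2.0 A of exactly one core heavy atom")
    } else if (min(d_all) > 2.0) {
      # multi-atom caps extend beyond 2 A of the core; require connectivity
      # to the rest of the fragment instead
      stop("cap atom ", frag$caps$name[i], " of ", frag$fragment_id,
           " is detached (> 2.0 A from every other fragment atom)")
    }
    if (any(d_all < 0.5))
      stop("cap atom ", frag$caps$name[i], " of ", frag$fragment_id,
           " clashes (< 0.5 A) with another fragment atom")
  }
  invisible(frag)
}

#' Select near-ligand waters as three-atom fragments
#'
#' Each water molecule whose minimum heavy-atom distance to any ligand atom
#' is within `cutoff` becomes one neutral fragment; waters beyond the
#' cutoff are excluded and counted in the `"excluded"` attribute.
#'
#' @param model a `protofibril`.
#' @param cutoff selection radius in Angstrom (default 6; `Inf` keeps all).
#' @param ligand optional ligand atom data frame; defaults to the model's
#'   ligand-class atoms.
#' @return list of `fragment` objects with attribute `excluded` (count).
#' @export
fragment_waters <- function(model, cutoff = 6, ligand = NULL) {
  if (is.null(ligand)) ligand <- model_atoms(model, "ligand")
  waters <- model_atoms(model, "water")
  out <- list()
  excluded <- 0L
  if (nrow(waters)) {
    if (nrow(ligand) == 0L)
      stop("no ligand atoms to measure water distances against")
    lig_xyz <- atom_coords(ligand)
    key <- residue_key(waters)
    for (k in unique(key)) {
      w <- waters[key == k, , drop = FALSE]
      o <- w[w$element == "O", , drop = FALSE]
      if (nrow(o) != 1L)
        stop("water residue ", w$chain_id[1], ":", w$res_seq[1],
             " has ", nrow(o), " oxygen atoms (expected 1)")
      heavy <- atom_coords(w[w$element != "H", , drop = FALSE])
      dmin <- min(apply(heavy, 1, function(p)
        min(sqrt(rowSums(sweep(lig_xyz, 2, p)^2)))))
      if (dmin <= cutoff) {
        w$cap_bond <- NA_character_
        out[[length(out) + 1L]] <- new_fragment(
          fragment_id = paste0(w$chain_id[1], ":", w$res_seq[1], ":", w$res_name[1]),
          core = w, caps = w[0, , drop = FALSE], net_charge = 0L,
          source_residues = data.frame(chain_id = w$chain_id[1],
                                       res_seq = w$res_seq[1],
                                       res_name = w$res_name[1],
                                       stringsAsFactors = FALSE))
      } else {
        excluded <- excluded + 1L
      }
    }
  }
  attr(out, "excluded") <- excluded
  out
}

#' Export fragments as a multi-structure XYZ file
#'
#' One XYZ block per fragment; the comment line carries the fragment id,
#' net charge and spin multiplicity.
#'
#' @param fragments list of `fragment` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragments_xyz <- function(fragments, path) {
  blocks <- unlist(lapply(fragments, function(f) {
    a <- fragment_atoms(f)
    c(nrow(a),
      sprintf("%s charge=%d multiplicity=%d", f$fragment_id, f$net_charge,
              f$multiplicity),
      sprintf("%-2s %14.8f %14.8f %14.8f", a$element, a$x, a$y, a$z))
  }))
  writeLines(blocks, path)
  invisible(path)
}
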