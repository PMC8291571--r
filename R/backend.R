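# ---- energy backend contract -----------------------------------------------

# fixed physical constants, chosen once for bit-reproducibility
COULOMB_K <- 332.0636          # kcal * Angstrom / (mol * e^2)
HARTREE_KCAL <- 627.509474     # kcal/mol per hartree

#' Capabilities of an energy backend
#'
#' @param backend an `energy_backend`.
#' @return character vector drawn from `"total_energy"`,
#'   `"cross_interaction"`.
#' @export
backend_capabilities <- function(backend) backend$capabilities

has_capability <- function(backend, cap) cap %in% backend$capabilities

#' Cross-interaction energy between two atom sets
#'
#' Generic of the energy-backend contract: the interaction energy (kcal/mol)
#' between two geometries held fixed, for backends advertising the
#' `"cross_interaction"` capability.
#'
#' @param backend an `energy_backend`.
#' @param atoms_a,atoms_b atom data frames.
#' @return named numeric vector `c(total=, elec=, vdw=)` in kcal/mol
#'   (component entries may be `NA` for backends without a split).
#' @export
cross_energy <- function(backend, atoms_a, atoms_b) UseMethod("cross_energy")

#' Total energy of one atom set
#'
#' Generic of the energy-backend contract, for backends advertising the
#' `"total_energy"` capability.
#'
#' @inheritParams cross_energy
#' @param atoms atom data frame.
#' @return named numeric vector `c(total=, elec=, vdw=)` in kcal/mol.
#' @export
total_energy <- function(backend, atoms) UseMethod("total_energy")

#' @export
print.energy_backend <- function(x, ...) {
  cat("energy backend:", x$method_label, "\n  capabilities:",
      paste(x$capabilities, collapse = ", "), "\n")
  invisible(x)
}

# ---- exact classical nonbonded backend -------------------------------------

#' Exact classical nonbonded backend
#'
#' Pairwise Coulomb plus Lennard-Jones energies with no cutoff, no switching
#' and no periodicity: exactness at desk scale is the point, since this
#' backend doubles as the oracle for the fragment-additivity identity.
#' Lorentz-Berthelot combining rules (arithmetic sigma, geometric epsilon)
#' and a Coulomb constant of 332.0636 kcal A / (mol e^2) are used.
#'
#' @return an object of class `c("classical_backend", "energy_backend")`.
#' @export
classical_backend <- function() {
  structure(list(capabilities = c("total_energy", "cross_interaction"),
                 method_label = "classical nonbonded (Coulomb + Lennard-Jones, no cutoff)"),
            class = c("classical_backend", "energy_backend"))
}

check_parameterized <- function(atoms, what) {
  need <- c("charge", "lj_sigma", "lj_epsilon")
  bad <- !stats::complete.cases(atoms[, need, drop = FALSE])
  if (any(bad)) {
    i <- which(bad)[1]
    stop("atom without nonbonded parameters in ", what, ": ",
         atoms$res_name[i], " ", atoms$chain_id[i], ":", atoms$res_seq[i],
         " ", atoms$name[i])
  }
  invisible(atoms)
}

pairwise_terms <- function(xyz_a, q_a, s_a, e_a, xyz_b, q_b, s_b, e_b) {
  dx <- outer(xyz_a[, 1], xyz_b[, 1], "-")
  dy <- outer(xyz_a[, 2], xyz_b[, 2], "-")
  dz <- outer(xyz_a[, 3], xyz_b[, 3], "-")
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  list(r = r,
       elec = COULOMB_K * outer(q_a, q_b) / r,
       vdw = {
         sij <- outer(s_a, s_b, "+") / 2
         eij <- sqrt(outer(e_a, e_b))
         x6 <- (sij / r)^6
         4 * eij * (x6 * x6 - x6)
       })
}

#' @rdname cross_energy
#' @export
cross_energy.classical_backend <- function(backend, atoms_a, atoms_b) {
  check_parameterized(atoms_a, "set A")
  check_parameterized(atoms_b, "set B")
  p <- pairwise_terms(atom_coords(atoms_a), atoms_a$charge, atoms_a$lj_sigma,
                      atoms_a$lj_epsilon,
                      atom_coords(atoms_b), atoms_b$charge, atoms_b$lj_sigma,
                      atoms_b$lj_epsilon)
  if (any(p$r < 1e-6))
    stop("overlapping atoms (r < 1e-6 A) between the two sets")
  elec <- sum(p$elec); vdw <- sum(p$vdw)
  c(total = elec + vdw, elec = elec, vdw = vdw)
}

#' @rdname total_energy
#' @export
total_energy.classical_backend <- function(backend, atoms) {
  check_parameterized(atoms, "atom set")
  n <- nrow(atoms)
  if (n < 2L) return(c(total = 0, elec = 0, vdw = 0))
  xyz <- atom_coords(atoms)
  p <- pairwise_terms(xyz, atoms$charge, atoms$lj_sigma, atoms$lj_epsilon,
                      xyz, atoms$charge, atoms$lj_sigma, atoms$lj_epsilon)
  up <- upper.tri(p$r)
  if (any(p$r[up] < 1e-6))
    stop("overlapping atoms (r < 1e-6 A) in the set")
  elec <- sum(p$elec[up]); vdw <- sum(p$vdw[up])
  c(total = elec + vdw, elec = elec, vdw = vdw)
}

#' Classical cross-interaction energy (convenience wrapper)
#'
#' Direct functional form of the classical backend, exposed for oracle use:
#' `sum_ij [ k q_i q_j / r_ij + 4 eps_ij ((sig_ij/r_ij)^12 - (sig_ij/r_ij)^6) ]`.
#'
#' @param atoms_a,atoms_b parameterized atom data frames.
#' @return named numeric vector `c(total=, elec=, vdw=)`.
#' @export
classical_cross_energy <- function(atoms_a, atoms_b) {
  cross_energy(classical_backend(), atoms_a, atoms_b)
}

#' Classical pairwise total energy (convenience wrapper)
#'
#' Intermolecular-style pairwise sum over all distinct pairs of one set with
#' the same Coulomb + Lennard-Jones form and no bonded terms; it exists only
#' to realise the supramolecular difference
#' `E(A united B) - E(A) - E(B)`.
#'
#' @param atoms parameterized atom data frame.
#' @return named numeric vector `c(total=, elec=, vdw=)`.
#' @export
classical_total_energy <- function(atoms) {
  total_energy(classical_backend(), atoms)
}

# ---- function-wrapped backend ----------------------------------------------

#' Wrap plain R functions as an energy backend
#'
#' Adapter for plugging an arbitrary energy callable (an external engine
#' driver, a stub in tests) into the backend contract.
#'
#' @param cross_fn optional `function(atoms_a, atoms_b)` returning kcal/mol.
#' @param total_fn optional `function(atoms)` returning kcal/mol.
#' @param method_label descriptive label.
#' @return an `energy_backend`.
#' @export
function_backend <- function(cross_fn = NULL, total_fn = NULL,
                             method_label = "user function backend") {
  caps <- c(if (!is.null(total_fn)) "total_energy",
            if (!is.null(cross_fn)) "cross_interaction")
  if (length(caps) == 0L) stop("at least one of cross_fn, total_fn is required")
  structure(list(capabilities = caps, method_label = method_label,
                 cross_fn = cross_fn, total_fn = total_fn),
            class = c("function_backend", "energy_backend"))
}

as_energy_terms <- function(v) {
  if (length(v) == 1L && is.null(names(v))) return(c(total = as.numeric(v), elec = NA_real_, vdw = NA_real_))
  out <- c(total = NA_real_, elec = NA_real_, vdw = NA_real_)
  out[intersect(names(v), names(out))] <- v[intersect(names(v), names(out))]
  if (is.na(out["total"])) out["total"] <- sum(out[c("elec", "vdw")])
  out
}

#' @rdname cross_energy
#' @export
cross_energy.function_backend <- function(backend, atoms_a, atoms_b) {
  if (is.null(backend$cross_fn)) stop("backend has no cross_interaction capability")
  as_energy_terms(backend$cross_fn(atoms_a, atoms_b))
}

#' @rdname total_energy
#' @export
total_energy.function_backend <- function(backend, atoms) {
  if (is.null(backend$total_fn)) stop("backend has no total_energy capability")
  as_energy_terms(backend$total_fn(atoms))
}

# ---- QM deck writing / result parsing --------------------------------------

#' Settings for external quantum-chemistry decks
#'
#' @param method electronic-structure method label (default `"M06-2X"`).
#' @param basis basis-set label, passed through as a free string
#'   (default `"6-31+G**"`).
#' @return a `qm_job_spec` list.
#' @export
qm_job_spec <- function(method = "M06-2X", basis = "6-31+G**") {
  structure(list(method = method, basis = basis), class = "qm_job_spec")
}

write_deck <- function(path, spec, charge, multiplicity, atoms) {
  stopifnot(multiplicity >= 1, nrow(atoms) > 0)
  lines <- c(
    sprintf("method %s", spec$method),
    sprintf("basis %s", spec$basis),
    sprintf("charge %d", as.integer(charge)),
    sprintf("multiplicity %d", as.integer(multiplicity)),
    "geometry",
    sprintf("%-2s %14.8f %14.8f %14.8f", atoms$element, atoms$x, atoms$y, atoms$z),
    "end")
  writeLines(lines, path)
  path
}

sanitize_id <- function(id) gsub("[^A-Za-z0-9._-]", "_", id)

#' Write quantum-chemistry input decks for a fragment set
#'
#' For each fragment three supramolecular decks are produced: the
#' fragment-ligand complex (charge = fragment charge + ligand charge), the
#' fragment alone, and the ligand alone (written once). The deck layout is
#' a stable plain-text format: `method`/`basis` header lines, `charge` and
#' `multiplicity` lines, then element/x/y/z rows between `geometry` and
#' `end`.
#'
#' @param fragments list of `fragment` objects.
#' @param ligand ligand atom data frame.
#' @param spec a [qm_job_spec()].
#' @param out_dir output directory (created if needed).
#' @param ligand_charge net formal charge of the ligand.
#' @param ligand_multiplicity spin multiplicity of the ligand.
#' @return manifest data frame (`fragment_id`, `complex`, `fragment`,
#'   `ligand` deck paths) with the ligand deck path as attribute
#'   `"ligand_deck"`; also written as `manifest.tsv` in `out_dir`.
#' @export
write_qm_decks <- function(fragments, ligand, spec = qm_job_spec(), out_dir,
                           ligand_charge = 0, ligand_multiplicity = 1) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  lig_path <- file.path(out_dir, "ligand.inp")
  write_deck(lig_path, spec, ligand_charge, ligand_multiplicity, ligand)
  rows <- lapply(fragments, function(f) {
    fa <- fragment_atoms(f)
    base <- sanitize_id(f$fragment_id)
    fp <- file.path(out_dir, paste0(base, "_frag.inp"))
    cp <- file.path(out_dir, paste0(base, "_complex.inp"))
    write_deck(fp, spec, f$net_charge, f$multiplicity, fa)
    write_deck(cp, spec, f$net_charge + ligand_charge,
               max(f$multiplicity, ligand_multiplicity),
               bind_atom_frames(fa, ligand))
    data.frame(fragment_id = f$fragment_id, complex = cp, fragment = fp,
               ligand = lig_path, stringsAsFactors = FALSE)
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(fragment_id = character(), complex = character(),
               fragment = character(), ligand = character(),
               stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  attr(manifest, "ligand_deck") <- lig_path
  manifest
}

read_final_energy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hits <- grep("FINAL ENERGY:", lines, value = TRUE)
  if (length(hits) == 0L)
    stop("no 'FINAL ENERGY: <value> hartree' line in ", path)
  m <- regmatches(hits[length(hits)],
                  regexec("FINAL ENERGY:\\s*([-+0-9.eEdD]+)\\s*hartree", hits[length(hits)]))[[1]]
  v <- suppressWarnings(as.numeric(gsub("[dD]", "e", m[2])))
  if (length(m) < 2L || is.na(v))
    stop("unparseable FINAL ENERGY line in ", path)
  v
}

#' Parse external quantum-chemistry results for a deck manifest
#'
#' Each deck `<name>.inp` is matched to a result file `<name>.out` in
#' `results_dir` containing a `FINAL ENERGY: <value> hartree` line; the last
#' such line wins. Energies are converted to kcal/mol at 627.509474
#' kcal/mol per hartree. Fragments with any missing result file are listed
#' in the `"gaps"` attribute rather than raising an error.
#'
#' @param manifest manifest from [write_qm_decks()].
#' @param results_dir directory holding the `.out` files.
#' @return data frame `fragment_id`, `e_complex`, `e_fragment`, `e_ligand`,
#'   `delta_e` (all kcal/mol), complete rows only, with attribute `gaps`
#'   (character vector of fragment ids lacking results).
#' @export
parse_qm_results <- function(manifest, results_dir) {
  result_path <- function(deck)
    file.path(results_dir, sub("\\.inp$", ".out", basename(deck)))
  energy_or_na <- function(deck) {
    p <- result_path(deck)
    if (!file.exists(p)) return(NA_real_)
    read_final_energy(p) * HARTREE_KCAL
  }
  lig_deck <- attr(manifest, "ligand_deck")
  if (is.null(lig_deck)) lig_deck <- manifest$ligand[1]
  e_lig <- if (length(lig_deck)) energy_or_na(lig_deck) else NA_real_
  out <- data.frame(fragment_id = manifest$fragment_id,
                    e_complex = vapply(manifest$complex, energy_or_na, 0.0,
                                       USE.NAMES = FALSE),
                    e_fragment = vapply(manifest$fragment, energy_or_na, 0.0,
                                        USE.NAMES = FALSE),
                    e_ligand = e_lig, stringsAsFactors = FALSE)
  out$delta_e <- out$e_complex - out$e_fragment - out$e_ligand
  gaps <- out$fragment_id[!stats::complete.cases(out)]
  out <- out[stats::complete.cases(out), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "gaps") <- gaps
  out
}
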