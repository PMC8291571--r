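# ---- per-fragment interaction records --------------------------------------

# rbind atom frames that may differ in auxiliary columns (mol_class etc.)
bind_atom_frames <- function(a, b) {
  common <- intersect(names(a), names(b))
  rbind(a[, common, drop = FALSE], b[, common, drop = FALSE])
}

record_columns <- function() {
  data.frame(fragment_id = character(), filament_id = character(),
             kind = character(), res_seq_1 = integer(), res_name_1 = character(),
             res_seq_2 = integer(), res_name_2 = character(),
             delta_e = double(), elec = double(), vdw = double(),
             stringsAsFactors = FALSE)
}

#' Interaction energy of one fragment with the ligand
#'
#' Evaluates the supramolecular interaction energy of a capped fragment
#' with the ligand on the fixed input geometry. When the backend provides
#' direct cross-interaction energies, `delta_e = cross(fragment, ligand)`;
#' otherwise the total-energy difference
#' `E(fragment+ligand) - E(fragment) - E(ligand)` is used. For a strictly
#' pairwise-additive backend the two routes are identical.
#'
#' @param fragment a `fragment`.
#' @param ligand ligand atom data frame.
#' @param backend an `energy_backend`.
#' @param zero_cap_params pass-through to [fragment_atoms()].
#' @return one-row record data frame (`fragment_id`, `filament_id`, `kind`,
#'   source residues, `delta_e` and its `elec`/`vdw` split when available).
#' @export
fragment_interaction <- function(fragment, ligand, backend = classical_backend(),
                                 zero_cap_params = FALSE) {
  fa <- fragment_atoms(fragment, zero_cap_params = zero_cap_params)
  e <- tryCatch({
    if (has_capability(backend, "cross_interaction")) {
      cross_energy(backend, fa, ligand)
    } else if (has_capability(backend, "total_energy")) {
      total_energy(backend, bind_atom_frames(fa, ligand)) -
        total_energy(backend, fa) - total_energy(backend, ligand)
    } else {
      stop("backend provides neither cross_interaction nor total_energy")
    }
  }, error = function(cnd) {
    stop("energy evaluation failed for fragment ", fragment$fragment_id, ": ",
         conditionMessage(cnd))
  })
  e <- as_energy_terms(e)
  if (!is.finite(e[["total"]]))
    stop("non-finite interaction energy for fragment ", fragment$fragment_id)
  sr <- fragment$source_residues
  is_water <- all(sr$res_name %in% WATER_RESNAMES)
  data.frame(
    fragment_id = fragment$fragment_id,
    filament_id = sr$chain_id[1],
    kind = if (is_water) "water" else "protein",
    res_seq_1 = sr$res_seq[1], res_name_1 = sr$res_name[1],
    res_seq_2 = if (nrow(sr) > 1L) sr$res_seq[2] else NA_integer_,
    res_name_2 = if (nrow(sr) > 1L) sr$res_name[2] else NA_character_,
    delta_e = e[["total"]], elec = e[["elec"]], vdw = e[["vdw"]],
    stringsAsFactors = FALSE
  )
}

new_interaction_summary <- function(records, delta_e_solvent = 0,
                                    three_body_correction = 0, meta = list()) {
  prot <- records$delta_e[records$kind == "protein"]
  wat <- records$delta_e[records$kind == "water"]
  delta_e_fibril <- sum(prot)
  if (abs(sum(wat) - delta_e_solvent) > 1e-9)
    stop("solvent total does not match water records")
  obj <- list(records = records,
              delta_e_fibril = delta_e_fibril,
              delta_e_solvent = delta_e_solvent,
              three_body_correction = three_body_correction,
              delta_e_total = delta_e_fibril + delta_e_solvent +
                three_body_correction,
              meta = meta)
  class(obj) <- "interaction_summary"
  obj
}

#' Fibril-ligand interaction energy as a fragment sum
#'
#' The total fibril-ligand interaction energy is the sum of the
#' per-fragment interaction energies; the per-fragment records are retained
#' for residue-wise decomposition.
#'
#' @param fragments list of protein `fragment`s (monopeptide fragmentation).
#' @param ligand ligand atom data frame.
#' @param backend an `energy_backend`.
#' @param zero_cap_params pass-through to [fragment_atoms()].
#' @param meta optional metadata list stored on the summary.
#' @return an `interaction_summary` with zero solvent term.
#' @export
total_fibril_interaction <- function(fragments, ligand,
                                     backend = classical_backend(),
                                     zero_cap_params = FALSE, meta = list()) {
  if (length(fragments) == 0L) {
    warning("empty fragment list: fibril interaction energy is 0")
    return(new_interaction_summary(record_columns(), meta = meta))
  }
  records <- do.call(rbind, lapply(fragments, fragment_interaction,
                                   ligand = ligand, backend = backend,
                                   zero_cap_params = zero_cap_params))
  new_interaction_summary(records, meta = meta)
}

#' Explicit-solvent ligand interaction energy
#'
#' Sum of per-water supramolecular interaction energies with the ligand,
#' the explicit-solvent counterpart of an implicit solvation term.
#'
#' @param water_fragments list of water `fragment`s from [fragment_waters()].
#' @inheritParams total_fibril_interaction
#' @return numeric `delta_e_solvent` (kcal/mol) with per-water records as
#'   attribute `records`.
#' @export
solvent_interaction <- function(water_fragments, ligand,
                                backend = classical_backend()) {
  if (length(water_fragments) == 0L) {
    r <- record_columns()
  } else {
    r <- do.call(rbind, lapply(water_fragments, fragment_interaction,
                               ligand = ligand, backend = backend))
  }
  structure(sum(r$delta_e), records = r)
}

#' Three-body correction from dipeptide windows
#'
#' Non-additivity captured by comparing each dipeptide-window interaction
#' energy with the sum of its two monopeptide constituents:
#' `sum_i [ dE(dipeptide_i) - dE(fragment_i) - dE(fragment_{i+1}) ]`.
#' With a strictly pairwise-additive backend and zero-parameter caps the
#' correction vanishes identically.
#'
#' @param monopeptide_records record data frame from monopeptide fragments.
#' @param dipeptide_records record data frame from dipeptide fragments.
#' @return the correction in kcal/mol.
#' @export
three_body_correction <- function(monopeptide_records, dipeptide_records) {
  mono_key <- paste(monopeptide_records$filament_id, monopeptide_records$res_seq_1)
  lookup <- function(filament, res_seq) {
    m <- which(mono_key == paste(filament, res_seq))
    if (length(m) != 1L)
      stop("dipeptide window ", filament, ":", res_seq,
           " has no matching monopeptide fragment")
    monopeptide_records$delta_e[m]
  }
  if (nrow(dipeptide_records) == 0L) return(0)
  if (any(is.na(dipeptide_records$res_seq_2)))
    stop("dipeptide record without a second residue")
  sum(vapply(seq_len(nrow(dipeptide_records)), function(i) {
    d <- dipeptide_records[i, ]
    d$delta_e - lookup(d$filament_id, d$res_seq_1) -
      lookup(d$filament_id, d$res_seq_2)
  }, 0.0))
}

# ---- top-level driver ------------------------------------------------------

#' Fragment-based decomposition of a complex
#'
#' End-to-end driver: fragments every protein chain of the model
#' (monopeptide windows; dipeptide windows additionally when
#' `order = "dipeptide"`, contributing a three-body correction), selects
#' waters within `water_cutoff` of the ligand, evaluates all per-fragment
#' ligand interaction energies with the chosen backend and aggregates them
#' into fibril, solvent and total interaction energies.
#'
#' @param model a parameterized `protofibril` containing ligand-class atoms
#'   (see [assign_parameters()] and the `ligand_resnames` argument of
#'   [read_pdb()]).
#' @param backend an `energy_backend`.
#' @param scheme capping scheme, see [fragment_chain()].
#' @param order `"monopeptide"` or `"dipeptide"`.
#' @param water_cutoff water selection radius in Angstrom (`Inf` keeps all).
#' @param his_charge,charge_rules,cap_params pass-through to
#'   [fragment_chain()].
#' @param zero_cap_params evaluate caps with zeroed parameters (testing
#'   switch; see [fragment_atoms()]).
#' @return an `interaction_summary`: per-fragment records (protein and
#'   water), `delta_e_fibril`, `delta_e_solvent`, `three_body_correction`
#'   and their sum `delta_e_total`, plus run metadata.
#' @export
decompose_complex <- function(model, backend = classical_backend(),
                              scheme = c("hydrogen", "methylamide"),
                              order = c("monopeptide", "dipeptide"),
                              water_cutoff = 6, his_charge = 0,
                              charge_rules = NULL, cap_params = TRUE,
                              zero_cap_params = FALSE) {
  scheme <- match.arg(scheme)
  order <- match.arg(order)
  ligand <- model_atoms(model, "ligand")
  if (nrow(ligand) == 0L) stop("model contains no ligand-class atoms")

  rt <- residue_table(model)
  chains <- unique(rt$chain_id[rt$mol_class == "protein"])
  frag_args <- list(scheme = scheme, his_charge = his_charge,
                    charge_rules = charge_rules, cap_params = cap_params)
  mono <- unlist(lapply(chains, function(cid)
    do.call(fragment_chain, c(list(model, cid, order = "monopeptide"), frag_args))),
    recursive = FALSE)
  records <- do.call(rbind, lapply(mono, fragment_interaction, ligand = ligand,
                                   backend = backend,
                                   zero_cap_params = zero_cap_params))

  three_body <- 0
  if (order == "dipeptide") {
    di <- unlist(lapply(chains, function(cid)
      do.call(fragment_chain, c(list(model, cid, order = "dipeptide"), frag_args))),
      recursive = FALSE)
    di_records <- do.call(rbind, lapply(di, fragment_interaction,
                                        ligand = ligand, backend = backend,
                                        zero_cap_params = zero_cap_params))
    three_body <- three_body_correction(records, di_records)
  }

  wfrags <- fragment_waters(model, cutoff = water_cutoff)
  e_solv <- solvent_interaction(wfrags, ligand, backend = backend)
  records <- rbind(records, attr(e_solv, "records"))

  new_interaction_summary(
    records, delta_e_solvent = as.numeric(e_solv),
    three_body_correction = three_body,
    meta = list(backend = backend$method_label, scheme = scheme, order = order,
                water_cutoff = water_cutoff,
                waters_excluded = attr(wfrags, "excluded"),
                counterpoise = "not applied",
                snapshot = "single fixed geometry")
  )
}

#' Average interaction summaries over snapshots
#'
#' Thin loop over per-snapshot summaries from the same system (identical
#' fragment ids): per-fragment mean and standard deviation of the
#' interaction energy, plus averaged aggregates. The default analysis is a
#' single snapshot; this helper supports averaging over several fixed
#' geometries of the same complex.
#'
#' @param summaries list of `interaction_summary` objects with matching
#'   fragment ids.
#' @return list with `records` (fragment_id, mean, sd, n) and averaged
#'   `delta_e_fibril`, `delta_e_solvent`, `three_body_correction`,
#'   `delta_e_total`.
#' @export
average_summaries <- function(summaries) {
  stopifnot(length(summaries) >= 1L)
  ids <- summaries[[1]]$records$fragment_id
  for (s in summaries) {
    if (!identical(s$records$fragment_id, ids))
      stop("summaries have mismatched fragment ids; are they the same system?")
  }
  e <- vapply(summaries, function(s) s$records$delta_e, numeric(length(ids)))
  e <- matrix(e, nrow = length(ids))
  list(
    records = data.frame(
      fragment_id = ids,
      mean = rowMeans(e),
      sd = apply(e, 1, stats::sd),
      n = length(summaries), stringsAsFactors = FALSE),
    delta_e_fibril = mean(vapply(summaries, `[[`, 0.0, "delta_e_fibril")),
    delta_e_solvent = mean(vapply(summaries, `[[`, 0.0, "delta_e_solvent")),
    three_body_correction = mean(vapply(summaries, `[[`, 0.0,
                                        "three_body_correction")),
    delta_e_total = mean(vapply(summaries, `[[`, 0.0, "delta_e_total"))
  )
}

# ---- summary methods and export --------------------------------------------

#' @export
print.interaction_summary <- function(x, ...) {
  cat("fragment interaction summary\n")
  cat(sprintf("  fragments: %d protein, %d water\n",
              sum(x$records$kind == "protein"), sum(x$records$kind == "water")))
  cat(sprintf("  dE_fibril  = %10.4f kcal/mol\n", x$delta_e_fibril))
  cat(sprintf("  dE_solvent = %10.4f kcal/mol\n", x$delta_e_solvent))
  if (x$three_body_correction != 0)
    cat(sprintf("  three-body = %10.4f kcal/mol\n", x$three_body_correction))
  cat(sprintf("  dE_total   = %10.4f kcal/mol\n", x$delta_e_total))
  invisible(x)
}

#' @export
summary.interaction_summary <- function(object, top_n = 5, ...) {
  print(object)
  n <- min(top_n, nrow(object$records))
  if (n > 0) {
    cat("\nmost stabilising fragments:\n")
    ord <- order(object$records$delta_e)[seq_len(n)]
    print(object$records[ord, c("fragment_id", "res_name_1", "delta_e")],
          row.names = FALSE)
  }
  invisible(object)
}

#' @export
as.data.frame.interaction_summary <- function(x, ...) x$records

#' Write an interaction summary as TSV
#'
#' One row per fragment record followed by the aggregate rows
#' (`dE_fibril`, `dE_solvent`, `three_body`, `dE_total`). Numeric fields
#' use a fixed format so identical inputs give byte-identical files.
#'
#' @param summary an `interaction_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interaction_tsv <- function(summary, path) {
  r <- summary$records
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.6f", v))
  header <- paste(c("fragment_id", "filament_id", "kind", "res_seq_1",
                    "res_name_1", "res_seq_2", "res_name_2",
                    "delta_e", "elec", "vdw"), collapse = "\t")
  rows <- sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
                  r$fragment_id, r$filament_id, r$kind,
                  ifelse(is.na(r$res_seq_1), "NA", r$res_seq_1), r$res_name_1,
                  ifelse(is.na(r$res_seq_2), "NA", r$res_seq_2),
                  ifelse(is.na(r$res_name_2), "NA", r$res_name_2),
                  fmt(r$delta_e), fmt(r$elec), fmt(r$vdw))
  agg <- sprintf("# %s\t%.6f", c("dE_fibril", "dE_solvent", "three_body", "dE_total"),
                 c(summary$delta_e_fibril, summary$delta_e_solvent,
                   summary$three_body_correction, summary$delta_e_total))
  writeLines(c(header, rows, agg), path)
  invisible(path)
}

#' Write an interaction summary as JSON
#'
#' @param summary an `interaction_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interaction_json <- function(summary, path) {
  jsonlite::write_json(
    list(records = summary$records,
         delta_e_fibril = summary$delta_e_fibril,
         delta_e_solvent = summary$delta_e_solvent,
         three_body_correction = summary$three_body_correction,
         delta_e_total = summary$delta_e_total,
         meta = summary$meta),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
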