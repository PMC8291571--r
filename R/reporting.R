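# ---- free-energy component bookkeeping -------------------------------------

GAS_CONSTANT_KCAL <- 1.98720425864083e-3   # kcal / (mol K)

#' Sum MM-GBSA style free-energy components
#'
#' The binding free energy is the sum of the gas-phase van der Waals and
#' electrostatic interaction energies and the polar (generalized-Born) and
#' nonpolar (surface-area) solvation terms. Vectorized; exact arithmetic.
#'
#' @param e_vdw,e_elec,g_gb,g_sa component energies in kcal/mol.
#' @return `g_binding` in kcal/mol.
#' @export
sum_free_energy_components <- function(e_vdw, e_elec, g_gb, g_sa) {
  stopifnot(all(is.finite(c(e_vdw, e_elec, g_gb, g_sa))))
  e_vdw + e_elec + g_gb + g_sa
}

#' Sum fibril and solvent interaction energies
#'
#' @param delta_e_fibril,delta_e_solvent energies in kcal/mol.
#' @return `delta_e_total` in kcal/mol.
#' @export
sum_interaction_totals <- function(delta_e_fibril, delta_e_solvent) {
  stopifnot(all(is.finite(c(delta_e_fibril, delta_e_solvent))))
  delta_e_fibril + delta_e_solvent
}

#' Inhibition constant from a binding free energy
#'
#' Uses the standard relation `dG = R T ln(Ki)` at a 1 M standard state,
#' so `Ki = exp(dG / (R T))` in mol/L with
#' R = 1.98720425864083e-3 kcal/(mol K). More negative binding free
#' energies give strictly smaller (tighter) inhibition constants.
#'
#' @param g_binding binding free energy in kcal/mol.
#' @param temperature absolute temperature in K (default 298.15).
#' @return Ki in mol/L.
#' @export
ki_from_free_energy <- function(g_binding, temperature = 298.15) {
  if (any(temperature <= 0)) stop("temperature must be positive (kelvin)")
  exp(g_binding / (GAS_CONSTANT_KCAL * temperature))
}

#' Binding free energy from an inhibition constant
#'
#' Inverse of [ki_from_free_energy()]: `dG = R T ln(Ki)` (Ki in mol/L,
#' 1 M standard state).
#'
#' @param ki inhibition constant in mol/L.
#' @param temperature absolute temperature in K.
#' @return binding free energy in kcal/mol.
#' @export
free_energy_from_ki <- function(ki, temperature = 298.15) {
  if (any(temperature <= 0)) stop("temperature must be positive (kelvin)")
  if (any(ki <= 0)) stop("Ki must be positive")
  GAS_CONSTANT_KCAL * temperature * log(ki)
}

# ---- residue-wise decomposition --------------------------------------------

#' Residue-wise decomposition of an interaction summary
#'
#' Attributes every fragment record to residues: monopeptide and water
#' records contribute their full energy to their residue; dipeptide-window
#' records are split 50/50 between their two residues (the attribution of
#' an overlapping window to its constituents is a reporting convention and
#' is documented as such). Rows are sorted by ascending energy (most
#' stabilising first) with ties broken by (filament_id, res_seq), and
#' ranked 1..n in that order.
#'
#' @param summary an `interaction_summary` with at least one record.
#' @param top_n how many most-stabilising residues to flag.
#' @return data frame `filament_id`, `res_seq`, `res_name`, `energy`,
#'   `rank`, `top` (logical).
#' @export
residue_decomposition <- function(summary, top_n = 5) {
  if (top_n < 1) stop("top_n must be >= 1")
  r <- summary$records
  if (nrow(r) == 0L) stop("summary has no records to decompose")
  halves <- !is.na(r$res_seq_2)
  rows <- rbind(
    data.frame(filament_id = r$filament_id, res_seq = r$res_seq_1,
               res_name = r$res_name_1,
               energy = ifelse(halves, r$delta_e / 2, r$delta_e),
               stringsAsFactors = FALSE),
    data.frame(filament_id = r$filament_id[halves],
               res_seq = r$res_seq_2[halves], res_name = r$res_name_2[halves],
               energy = r$delta_e[halves] / 2, stringsAsFactors = FALSE)
  )
  agg <- stats::aggregate(energy ~ filament_id + res_seq + res_name,
                          data = rows, FUN = sum)
  ord <- order(agg$energy, agg$filament_id, agg$res_seq)
  agg <- agg[ord, c("filament_id", "res_seq", "res_name", "energy")]
  rownames(agg) <- NULL
  agg$rank <- seq_len(nrow(agg))
  agg$top <- agg$rank <= top_n
  agg
}

#' Write a residue decomposition table as TSV
#'
#' Fixed numeric formatting: identical inputs give byte-identical output.
#'
#' @param decomposition data frame from [residue_decomposition()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_decomposition_tsv <- function(decomposition, path) {
  d <- decomposition
  lines <- c("filament_id\tres_seq\tres_name\tenergy\trank\ttop",
             sprintf("%s\t%d\t%s\t%.6f\t%d\t%s", d$filament_id, d$res_seq,
                     d$res_name, d$energy, d$rank, ifelse(d$top, "yes", "no")))
  writeLines(lines, path)
  invisible(path)
}

# ---- external component tables ---------------------------------------------

#' Load and check a free-energy component table
#'
#' Reads a delimited table (tab or comma, autodetected) of MM-GBSA style
#' binding free-energy components with columns `site`, `e_vdw`, `e_elec`,
#' `g_gb`, `g_sa`, `g_binding`, re-aggregates the four components and flags
#' rows whose printed total disagrees with the recomputed sum beyond `tol`.
#'
#' The default tolerance is 0.25 kcal/mol: published tables print each of
#' the four components and the total independently rounded to one decimal,
#' so a faithfully transcribed row can disagree with its recomputed sum by
#' up to 5 x 0.05 kcal/mol even when the underlying arithmetic is exact.
#'
#' @param path file path.
#' @param tol flagging tolerance in kcal/mol.
#' @return data frame with the input columns plus `g_recomputed`,
#'   `discrepancy` and logical `flagged`. Extra columns of the input are
#'   preserved.
#' @export
load_component_table <- function(path, tol = 0.25) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, strip.white = TRUE,
                           comment.char = "#")
  need <- c("site", "e_vdw", "e_elec", "g_gb", "g_sa", "g_binding")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("component table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(tab) == 0L) {
    warning("component table ", path, " has an empty data section")
    tab$g_recomputed <- numeric(0); tab$discrepancy <- numeric(0)
    tab$flagged <- logical(0)
    return(tab)
  }
  tab$g_recomputed <- sum_free_energy_components(tab$e_vdw, tab$e_elec,
                                                 tab$g_gb, tab$g_sa)
  tab$discrepancy <- tab$g_recomputed - tab$g_binding
  tab$flagged <- abs(tab$discrepancy) > tol
  tab
}
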