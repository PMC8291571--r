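---
title: "Fragment-based decomposition of fibril-ligand interaction energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-based decomposition of fibril-ligand interaction energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragdecomp)
```

## The problem

Amyloid fibrils — here, tau fibrils of the kind that accumulate in
Alzheimer's disease, chronic traumatic encephalopathy and Pick's disease —
bind small-molecule tracers such as AV-1451 in surface grooves and core
channels. Understanding *which residues* hold a tracer, and how strongly,
requires decomposing the fibril-ligand interaction energy residue by
residue. A fibril is far too large for a single electronic-structure
calculation, but because interaction energies are short-ranged and nearly
additive over well-separated groups, the fibril can be cut into small
closed-shell pieces whose individual interactions with the ligand are
tractable at any level of theory.

`fragdecomp` implements this fragmentation scheme as a reusable toolkit:

1. cleave every protein chain along its peptide bonds;
2. cap each piece so it is a sensible closed-shell molecule;
3. evaluate each fragment-ligand interaction energy with a pluggable
   backend;
4. sum the fragment contributions into the fibril term, add an
   explicit-solvent water term, and report residue-wise decomposition
   tables.

## The model

For a fragment $F$ and ligand $L$ on a *fixed* geometry, the
supramolecular interaction energy is

$$\Delta E(F, L) \;=\; E(F \cup L) - E(F) - E(L).$$

The fibril-ligand interaction energy is approximated as the sum over
monopeptide fragments,

$$\Delta E_{\mathrm{fibril}} = \sum_i \Delta E(F_i, L),$$

the solvent term as the sum over selected explicit waters,
$\Delta E_{\mathrm{solvent}} = \sum_w \Delta E(w, L)$, and the total as
$\Delta E_{\mathrm{total}} = \Delta E_{\mathrm{fibril}} +
\Delta E_{\mathrm{solvent}}$ (plus the three-body correction below when
requested). Every `interaction_summary` asserts these identities at
construction, to $10^{-9}$ kcal/mol.

All geometry is in Angstrom and all energies in kcal/mol. Energies are
evaluated on the input snapshot as-is — no relaxation, no averaging —
because the scheme is designed for single configurations drawn from a
simulation; `average_summaries()` provides the thin mean/sd loop when
several snapshots of the same system are available.

### Fragmentation and capping

Peptide bonds are detected by the C(i)–N(i+1) distance with a 1.8 A
cutoff: real peptide bonds are 1.32–1.35 A, so the cutoff tolerates
distorted geometries while treating genuinely separated residues as chain
breaks (reported as warnings, never silently bridged). Two capping schemes
close the cut valences:

* **hydrogen** (link atoms): the atom across the cut bond is replaced by a
  hydrogen placed *along the original bond vector*, at 1.09 A from the
  carbonyl carbon and 1.01 A from the amide nitrogen — the standard
  link-atom convention. One cap atom per cut side.
* **methylamide**: the N-terminal piece of a cut receives an N-methylamide
  (NH–CH$_3$) cap and the C-terminal piece an acetyl (CO–CH$_3$) cap. Cap
  heavy atoms reuse the positions of the original neighbouring backbone
  atoms, so fragment geometry stays faithful to the snapshot; only atoms
  that did not exist (methyl hydrogens, a missing amide hydrogen) are
  synthesised, with a deterministic tetrahedral construction whose
  azimuthal frame is fixed by the lab axis least aligned with the bond.

For hydrogen caps the package enforces that each cap lies within 2.0 A of
exactly one core heavy atom and at least 0.5 A from everything else. A
multi-atom methylamide cap structurally cannot satisfy the single-anchor
form of that rule (its methyl carbon sits ~2.4 A from the nearest core
heavy atom), so for that scheme the check is connectivity — every cap atom
within 2.0 A of at least one other fragment atom — plus the same 0.5 A
clash floor.

Fragment net charges are the sum of standard pH-7 side-chain formal
charges (ASP/GLU −1, LYS/ARG +1; histidine neutral by default, with
`his_charge` and `charge_rules` overrides because protonation is a
modelling choice, not a fact of the file). Terminal residues keep whatever
termini the input has: fibril cores are mid-sequence excerpts and forcing
zwitterions would fabricate charges. All fragments are closed-shell
singlets.

With `order = "dipeptide"`, overlapping two-residue windows are built, one
per *detected* peptide bond — a window never spans a chain break, since
there is no bond to keep intact there. The three-body correction is

$$\Delta_3 = \sum_i \left[\Delta E(F_{i,i+1}) - \Delta E(F_i) -
\Delta E(F_{i+1})\right],$$

which vanishes identically for a pairwise-additive backend (a property the
tests exploit) and captures non-additive polarisation for electronic
backends.

### Water selection

Waters are selected by minimum heavy-atom distance to any ligand atom,
default 6 A. The cutoff is configurable (including `Inf` for all waters)
and is recorded in the summary metadata, because the appropriate radius is
a judgement about how far explicit-solvent contributions matter for the
system at hand.

## Energy backends

The backend contract is two capabilities: `total_energy(atoms)` and/or
`cross_interaction(atoms_a, atoms_b)`, both in kcal/mol. When only totals
are available the supramolecular difference is formed; when direct cross
energies exist they are used; for a pairwise-additive backend the routes
agree to machine precision, and a test asserts it.

* **Classical backend** — exact pairwise Coulomb plus Lennard-Jones with
  Lorentz–Berthelot combining, *no* cutoffs, switching or periodicity.
  Constants are fixed for bit-reproducibility: Coulomb
  332.0636 kcal·A/(mol·e²), hartree 627.509474 kcal/mol. This backend is
  deliberately simple and exact at desk scale: it is the oracle against
  which the fragmentation identities are proven, not a force-field
  reproduction. Lennard-Jones parameters default from a small built-in
  per-element table; any per-(residue, atom) table supplied by the user
  overrides it.
* **QM deck writer / parser** — `write_qm_decks()` emits, per fragment,
  the complex / fragment / ligand deck triplet in a stable plain-text
  layout (method and basis headers, charge and multiplicity lines, element
  + coordinates), defaulting to M06-2X/6-31+G**, a functional/basis pair
  appropriate for dispersion-dominated fibril-tracer interactions. The
  basis is a free string because printed conventions vary (6-31+G* vs
  6-31+G**). `parse_qm_results()` reads `FINAL ENERGY: <value> hartree`
  lines, converts, and reports missing files as explicit gaps rather than
  failing the whole run. No counterpoise/BSSE correction is applied; the
  summaries say so in their metadata.

Cap atoms carry parameters in production runs — they are real atoms in the
electronic structure of each fragment. The `zero_cap_params` switch, which
zeroes cap charges and Lennard-Jones wells, exists *only* to make the
fragment sum exactly additive so tests can compare it against the direct
protein-ligand cross energy. With default cap parameters the residual
$|\sum_i \Delta E(F_i,L) - \Delta E(\mathrm{protein}, L)|$ is a real cap
sensitivity, reported by comparing the two quantities — never silently
dropped.

## Structure handling

PDB input is parsed by fixed columns with line-numbered errors, first
model only, and alternate locations resolved by highest occupancy (ties:
first encountered — wild-type PDB files demand *some* deterministic rule).
Residues classify as water (HOH/WAT/TIP3), ligand (user-supplied residue
codes), protein (standard amino acid with an N/CA/C backbone) or other.

Protofibril extension estimates the filament stacking operator by Kabsch
superposition of backbone atoms (N, CA, C only — robust to side-chain
disorder) of each consecutive chain pair, averages the rotations with a
projection back onto the rotation group, and applies the operator
repeatedly to the terminal chain. The operator is *derived from the
structure itself* rather than from deposited helical parameters: the
structures this is meant for do not always record those parameters, and
superposition works for any stack of near-identical chains. Reflections
are excluded (determinant +1 enforced); collinear point sets are an error,
not a silent arbitrary rotation.

## Free-energy bookkeeping and Ki

MM-GBSA style component tables (gas-phase van der Waals and electrostatic
terms plus generalized-Born and surface-area solvation) are re-aggregated
with exact sums. When *loading a printed table*, the check tolerance
defaults to 0.25 kcal/mol: each of the four components and the total are
independently rounded to one decimal in print, so a faithfully transcribed
row can disagree with its recomputed sum by up to 5 × 0.05 kcal/mol with
no arithmetic error anywhere. The shipped example table
(`inst/extdata/tau_av1451_mmgbsa_components.tsv`) contains rows that
disagree by exactly 0.1 kcal/mol for this reason; a tighter tolerance
would flag correct transcriptions.

Binding free energies convert to inhibition constants via
$\Delta G = RT \ln K_i$ at a 1 M standard state, with
$R = 1.98720425864083 \times 10^{-3}$ kcal/(mol·K). The relation is
rendered in this standard form; the standard-state assumption is stated
here and in the function documentation.

Residue-wise decomposition attributes each monopeptide or water record to
its residue and splits dipeptide-window records 50/50 between their two
residues — a reporting convention, chosen because overlapping windows have
no unique attribution. Rows are sorted most-stabilising-first with
deterministic (filament, residue) tie-breaking, and the rows always sum to
$\Delta E_{\mathrm{fibril}} + \Delta E_{\mathrm{solvent}}$.

## Synthetic fixtures, and what the tests do and do not show

`build_peptide()`/`build_complex()` generate deterministic toy systems:
ideal-geometry extended backbones (N–CA 1.46, CA–C 1.52, C–N 1.33,
C–O 1.23 A) optionally stacked by an exact screw operator with a
4.8 A rise, emulating the filament stacking of an amyloid protofibril; a
rigid two-atom or six-membered-ring probe ligand; waters on a seeded
jittered grid with a 2.5 A clash floor. Most atoms carry zero charge by
default so tests can *plant* a few charge carriers and know the expected
energy in closed form — the ±1 e pair at 3.320636 A giving exactly
−100 kcal/mol is the canonical example.

These fixtures deliberately omit side-chain rotamers, real fibril
geometry, hydrogens on the backbone and force-field-quality parameters.
Passing tests therefore demonstrate the *mathematics* of the scheme —
conservation of atoms and charge, exact additivity, cap geometry, operator
recovery — on clean inputs; they do not validate any force field or
quantum method against experiment, and real structures will exercise
messier parsing paths (alt-locs, breaks, non-standard residues) for which
the behaviour is defined above.

Problem sizes used by the shipped test-and-verification runs: twenty
seeded complexes of 3–8 residues, one or two chains and up to ten waters
for the additivity identities; three- to five-residue stacks for geometry
checks. These sizes are where closed-form bookkeeping stays exactly
checkable while still exercising every code path; the algorithms
themselves have no size-specific logic.

## Known limitations

* The classical backend is an oracle, not a force field: no bonded terms,
  no cutoff schemes, generic element Lennard-Jones defaults.
* Generalized-Born and surface-area solvation energies are ingested from
  external tables, never computed here.
* No disulfide-aware fragmentation; proline's N-cap follows the standard
  rule; non-standard residues need a user-supplied charge rule.
* mmCIF, crystallographic symmetry and multi-model ensembles (beyond
  first-model-with-warning) are out of scope.
* Chain identifiers are single characters (PDB fixed columns), limiting a
  model to 62 distinct chains.
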