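---
title: "Building biomass objective functions from composition data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building biomass objective functions from composition data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bofkit)
```

# The model and its assumptions

A biomass objective function (BOF) is the pseudo-reaction a genome-scale
metabolic model (GEM) maximizes to represent growth: it consumes every
precursor needed to build 1 g of cell dry weight (gDW). `bofkit` constructs
BOFs of up to three levels. The level-1 reaction consumes macromolecule
pools (and, optionally, directly measured metabolites such as glycogen) in
mmol·gDW⁻¹ and produces 1 unit of a biomass pseudo-metabolite. Level-2
reactions build each pool from monomers in mole fractions (mol per mol of
pool); level-3 reactions do the same one step deeper — the classic use case
being lipid classes (LIPIDS → PC, PE; PC → individual species).

The conversion pipeline rests on these assumptions:

* **Mass recovery defines the scale.** Whatever total mass the level-1 data
  recover, it is rescaled so that the total equals exactly 1 g per gDW
  (`scale_factor = 1 / total`). Normalization always happens; when the
  scale factor falls outside [0.8, 1.25] a warning notes that the recovered
  mass was far from 1 g, because that usually means a unit slip or a missing
  macromolecule rather than honest measurement noise.
* **Polymers are one monomer long.** A pool's molar mass is the plain
  mole-fraction-weighted monomer mass; no condensation water is subtracted.
  Dehydration and energy costs belong in the maintenance table, stated on
  the same one-monomer basis.
* **Maintenance rows are trusted verbatim.** They are used as stoichiometric
  coefficients directly (mmol·gDW⁻¹ on the level-1 sheet, mol per mol of
  pool on pool sheets), never converted and never rescaled by the mass
  normalization. The sign convention is the standard stoichiometric one:
  negative = consumed, positive = produced. The source data format this
  package emulates does not state how byproducts are marked; the signed
  convention is this package's documented choice, and the biggest single
  assumption a user migrating data should check.
* **Pseudo-metabolite formulas are nets.** Each generated pseudo-metabolite
  gets the formula and charge obtained by netting its own reaction
  (substrates minus non-pool products, maintenance included). This is the
  only choice that makes every generated reaction elementally and charge
  balanced *by construction*, and it propagates: when the maintenance rows
  are themselves elementally self-balanced (e.g. ATP + H₂O → ADP + Pᵢ + H⁺),
  the net mass consumed per unit flux of the top reaction is exactly 1 g.

# Units and parameters that matter

Composition tables accept seven units: `g_per_gDW`, `mg_per_gDW`,
`percent_DW_mass` (g per 100 g DW), `mmol_per_gDW`, `umol_per_gDW`,
`mol_per_mol`, `percent_mol` (mol per 100 mol of pool). One sheet, one unit:
units may differ across sheets but not within a composition table. Two
placement rules are enforced that the accepted-unit list alone would not
catch:

* level-1 sheets must use a per-gDW unit (the five first). `mol_per_mol` at
  level 1 has no dry-weight basis — there is no "mole of biomass" to be a
  fraction of — so it is rejected rather than guessed at.
* maintenance units are `mmol_per_gDW` on the level-1 sheet and
  `mol_per_mol_pool` on pool sheets, the only dimensionally consistent
  assignment given that maintenance rows are used verbatim.

Pool sheets accept any of the seven units: mass units are divided by the
constituent molar mass (model formula, or the child pool's computed mass)
before normalizing to mole fractions, so only ratios matter there.

Other tunables: `tol` of `balance_check()` (default `1e-6` absolute per
element; double-precision netting leaves residuals around `1e-9`, and the
margin absorbs file-serialization rounding); reaction bounds of generated
pseudo-reactions (fixed at `[0, 1000]`, the conventional irreversible COBRA
ceiling); and the `set_objective` flag (the model's objective is never
touched unless asked).

# Numerical choices

* All arithmetic is double precision; coefficients are never rounded
  internally. Model files carry 15 significant digits.
* Serialized formula counts carry up to 9 decimal places (trailing zeros
  trimmed, Hill element order). Six decimals — a plausible-looking default —
  was tried first and rejected: coefficient-weighted rounding errors of up
  to 5·10⁻⁷ per count accumulate past the 1e-6 balance tolerance on the
  level-1 reaction. Nine decimals keeps files diffable while reloaded models
  still balance to ~1e-8.
* A charge of `NA` means *unknown* and is contagious: any combination
  involving an unknown charge has an unknown charge, never a silent 0. The
  same holds for formulas. Declaring formulas/charges available
  (`formula_available`, `charge_available`) turns a missing one into an
  error instead of a warning, because downstream balance checks rely on the
  promise.
* Pseudo-element tokens occasionally found in GEM formulas (`R`, `X`) parse
  fine; they only fail — loudly, naming the element — if a molar mass is
  actually requested.
* Zero-valued composition rows are dropped with a logged notice (they
  cannot affect coefficients); duplicate metabolite IDs within one sheet are
  an error, never silently summed. Order is preserved everywhere: entries in
  sheet order, reactions in sheet order, so repeated runs produce
  byte-identical files.
* The FBA feasibility check solves the LP with a built-in dense two-phase
  simplex using Bland's rule. This exists because no LP library is assumed;
  it is dense and deliberately simple, fine for the bundled toy models and
  *not* intended for genome-scale networks. Degenerate systems are handled
  by eliminating fixed variables and reducing the equality rows to an
  independent subset (with an explicit consistency check) before solving.
* `growth_check()` temporarily adds a sink for the biomass pseudo-metabolite
  on an internal copy of the model: the generated top reaction produces one
  unit of that metabolite and nothing consumes it, so without a drain steady
  state would force zero flux under any medium. The caller's model is never
  modified.

# Design choices where the design was open

* **Two-table sheets, header-resolved.** The canonical on-disk format is a
  directory of TSV files (one per sheet; composition table, blank line,
  maintenance table; columns found by header name). XLSX workbooks with the
  same two-table layout are read when `readxl` is installed. Fixed cell
  coordinates were rejected in favour of named headers: testable, diffable,
  and self-documenting. No XLSX *writer* exists in the supported dependency
  set, so reports are TSV.
* **Root detection instead of a reserved name.** The level-1 sheet is the
  unique sheet referenced by no other sheet. "BIOMASS" is conventional, not
  required. The pool reference graph must be a tree of depth ≤ 3, each pool
  referenced exactly once, one level deeper than its consumer.
* **ID scheme.** Pseudo-metabolite and pseudo-reaction both get
  `<sheet>_<tag>`; the compartment is an attribute, not an ID suffix. Tags
  are `[A-Za-z0-9_]+`, so several BOFs can coexist and be removed cleanly by
  suffix match.
* **Atomic weights are bundled** (IUPAC 2021 standard weights, static table)
  so that balance checks cannot drift with an external package version.
* **Level-1 sheets may mix pools and plain metabolites** (e.g. glycogen
  measured directly next to the PROTEIN pool) — necessary for single-level
  BOFs to make sense at all.
* **Insertion is atomic.** All generated IDs are checked against the model
  before anything is added; on collision the model is returned untouched.

# What the synthetic fixtures emulate — and what they do not

`make_toy_model()` / `make_composition()` generate a deterministic toy
organism: one compartment, 18 metabolites with real (small) formulas and
integer charges, a three-level BOF over PROTEIN (4 amino acids), DNA
(4 dNTPs), LIPIDS → PC/PE (2 species each) and glycogen, maintenance rows
using the self-balanced ATP-hydrolysis quartet, level-1 masses drawn
randomly (seeded) and rescaled to sum to 0.97 g/gDW — deliberately not 1, so
the normalization path is always exercised. With `make_feasible`, every
metabolite gets an exchange reaction so the BOF can carry flux.

The fixtures exercise every conversion path, the balance machinery, and the
LP; they do **not** emulate realistic organism compositions, multi-
compartment models, missing/not-quite-Hill formula strings from the wild, or
genome-scale problem sizes. A green test suite establishes that the
arithmetic, normalization, balancing and I/O contracts hold — not that any
particular organism's BOF is biologically sensible.

# Known limitations

* SBML support is Level 3 + FBC v2, restricted to the constructs COBRA
  models actually circulate: compartments, species with formula/charge,
  reactions with flux-bound parameters, objectives. Annotations, groups and
  gene associations are out of scope (existing ones are not preserved
  through a load/save cycle).
* FBC v2 formally types `fbc:charge` as integer; netted pseudo-metabolite
  charges can be fractional and are written as decimals. cobrapy reads such
  files; strict validators may complain. The JSON dialect has no such
  restriction.
* Plain FBA stands in for parsimonious FBA in the feasibility check — the
  contract checked is only "optimum > 0", on which both agree.
* The built-in simplex is dense: models beyond a few hundred reactions will
  be slow.
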