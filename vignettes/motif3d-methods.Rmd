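---
title: "motif3d: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{motif3d: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motif3d)
```

This vignette records how the package's two components — the 3D pattern
search and the thermal-shift binding model — are defined, which choices
were genuinely open, and what the synthetic test surface does and does not
demonstrate.

## 1. The pattern language

A query is an alternating list of *sequence patterns* and *structural
connectors*, optionally closed into a ring. The grammar is deliberately
small: per-position residue logic (exact letter, `[allowed]`,
`{forbidden}`, `x` wildcard), per-connector distance and angle ranges, and
nothing else — no repetition quantifiers, no nested groups, no coordinate
templates. Expressivity is traded for ease of pattern writing and search
speed; the approach is sequence-pattern-driven rather than
template-coordinate-driven (contrast TESS/Jess-style geometric matching).

Decisions where the language definition was open:

* **`|` inside a connector is a conjunction.** `<3,8|60,120>` means the
  pair must satisfy the distance range *and* the angle range. Nothing in
  the language's worked usage requires disjunction, and conjunction is
  what makes a combined distance+angle restraint on one pair expressible.
  The first range is always the distance (Å); an optional second range is
  the angle (degrees).
* **Cyclic closure.** A trailing hyphen marks a cycle. If it follows a
  connector, that connector is the closing edge. If it follows a sequence
  pattern — as in `R-<2,6>-R-<4,5>-Y-` — the *last connector is reused*
  for the closing edge: the intent of such a query is that the final
  functionality sits between the two preceding ones, i.e. Y must satisfy
  the 4–5 Å constraint against the first arginine too, not merely close
  the ring topologically. Both forms render back to their original text
  (`closing_explicit` tracks which was written).
* **Wildcard and case.** `x`/`X` is the wildcard (PROSITE convention);
  all other residue letters are case-insensitive. Nonstandard residues
  surface as `X` in extracted sequences and are matched *only* by the
  wildcard.
* **Ranges are inclusive** on both ends, `[min, max]`.

Parsing is total: every string either yields a query object or a located
parse error (`motif3d_parse_error`), and `parse_query(render_query(q))`
is the identity — property-tested over seeded random queries.

## 2. Structure model

Structures are read from PDB or mmCIF (via bio3d), one model at a time.
HETATM records are excluded, as are residues lacking a Cα; sequences are
extracted per chain with a bijective map from 0-based index to author
numbering (matches are always *reported* in author numbering, while
overlap logic runs on half-open index intervals `[start, end)`).

* **Pseudo-points** are the unweighted centroid of the side-chain heavy
  atoms (everything except backbone N, Cα, C, O, OXT and hydrogens). The
  cited coarse-graining literature describes side-chain interaction
  centers "roughly" at the center of mass without a reference atom list;
  the unweighted centroid is the simplest deterministic choice and is
  within a few tenths of an Å of the mass-weighted point for all standard
  side chains. Glycine, and any residue with no resolved side-chain
  atoms, falls back to Cα (the latter with a load-time warning).
* **Alternate conformers** produce one anchor per altloc; the default
  policy `all` accepts an edge if *any* conformer pair satisfies it and
  records which pair did. This mirrors how a two-conformer arginine is
  legitimately part of a descriptor: either rotamer can present the
  functionality. `highest_occupancy` keeps a single anchor per residue.
* **Segment vectors** (for angle constraints): Cα(first)→Cα(last) for
  multi-residue segments, N→C of the single residue otherwise — the
  nearest well-defined "backbone direction" in each case.
* **Connector anchors for multi-residue patterns**: last residue of the
  left pattern, first residue of the right pattern. No worked multi-residue
  usage exists to pin this down; the chosen rule makes the constraint
  refer to the residues nearest each other in query order and reduces to
  the obvious rule for single-residue patterns.

`buried_area()` computes (SASA(A) + SASA(B) − SASA(A∪B))/2 by
Shrake–Rupley sampling with a fixed Chothia-style radii table (C 1.87 Å,
carbonyl C 1.76, N 1.65, O 1.40, S 1.85, default 1.80), probe 1.4 Å, 960
deterministic golden-spiral points per atom, hydrogens and heteroatoms
excluded, best-occupancy conformer per atom. A single isolated atom
reproduces its analytic sphere area exactly under this sampling; doubling
the point count moves a helix-pair interface by under 2 % (tested).
Published interface areas are convention-dependent at the ±10–15 % level
(radii table, probe, altloc handling), which is why the package treats
"about 800 Å²" as a band, not a point value.

## 3. Search engine

The matcher is staged: sequence pre-filter, occurrence index, recursive
backtracking.

The **pre-filter** is an assignment check, not a counting check: a
structure is a candidate only if a pairwise non-overlapping placement of
all patterns exists (counting would wrongly accept a sequence where two
patterns compete for the same residue).

**Backtracking** assigns one occurrence per pattern in query order, in
deterministic (chain, ascending index) traversal order, checking the
connector to the previous pattern immediately and pruning failed branches.
A diagnostic flag disables pruning; the match set is proven unchanged in
tests. The cyclic closing edge is checked when the final pattern is
placed.

**Non-overlap** operates at two levels: occurrences within one match are
pairwise disjoint, and — with `enumerate_all = FALSE` (default) — accepted
matches claim their residues so later matches cannot reuse any component.
This greedy policy is deterministic given the traversal order.

**Sequence-order freedom**: patterns may land in any sequence order and on
different chains. Published matches of the worked query map query order
R,R,Y onto ascending, descending, and interleaved author numbers, so no
monotonicity constraint is imposed. Single-chain and span restrictions
(≤ 10 residues) are *report filters* (`filter_report()`), not engine
constraints.

**Match identity.** Queries can be symmetric — in `R-<2,6>-R-<4,5>-Y-`
the two arginine patterns see identical constraint multisets, so for any
satisfying assignment the arginine-swapped assignment also satisfies. The
scientifically meaningful identity of a match is therefore its *residue
set*, which is how uniqueness is defined for planted-motif recovery
(`segment_set_signature()`) and how the greedy non-overlap rule behaves
(a swapped variant of an accepted match is consumed by it). Assignment
tuples remain the unit of comparison for engine-vs-oracle equivalence.

Corpus redundancy reduction is delegated to the user-supplied file list;
the engine neither downloads nor clusters structures.

## 4. Synthetic test surface

The generators define the conditions under which the engine is validated:

* `ideal_helix_structure()` — Cα on a parametric helix (defaults: rise
  1.5 Å, twist 100°, radius 2.3 Å: canonical α-helix values, giving the
  familiar 3.8 Å consecutive and ~6.2 Å *i*,*i*+4 contacts, both verified
  against the closed-form chord length), one synthetic radial side-chain
  atom per non-Gly residue, N/C at ±0.7 Å along the local tangent.
* `planted_motif_structure()` — solves segment translations so every
  distance edge of a (distance-only) query holds, targeting the interior
  of each range (margin 0.1 Å or a quarter of the range width) so the
  construction survives 3-decimal PDB coordinate rounding; filler
  residues use letters the query cannot match and sit 500 Å away.
  Uniqueness at residue-set level is verified by the brute-force oracle
  at construction; infeasible range sets (coincident anchors,
  triangle-inequality violations) raise `motif3d_infeasible`.
* `decoy_structure()` — self-avoiding random walk (step 3.8 Å, non-bonded
  minimum 4 Å) with random sequences; used for oracle-equivalence sweeps.
* `brute_force_search()` — exhaustive Cartesian-product enumeration with
  a 10^6-combination guard; the defining oracle for the engine.

What passing these tests shows: the engine is *exactly* equivalent to
enumeration on structures of this size, recovers constructed ground truth,
and never reports an edge that fails independent re-measurement. What it
does not show: behaviour on real side-chain rotamer distributions,
crystallographic disorder beyond simple altlocs, or insertion-code-heavy
numbering — the crystal-structure tests (section 6) cover real geometry
when the entries are available.

Problem sizes in the default suite and acceptance script — 200 structures
of ≤ 60 residues for oracle equivalence, 20 planted instances, 1000
parser round-trips, 50 melt-curve datasets — were chosen as the smallest
sets that exercise every code path with comfortable statistical margins.

## 5. Binding model

Assumptions, in order of importance:

1. **Two states** (native, denatured), `Ku = [denatured]/[native]`,
   `Ku(Tm) = 1`.
2. **Van't Hoff closure with ΔCp = 0**: the minimal temperature
   dependence consistent with a two-state equilibrium. No functional form
   is mandated by the printed model; this is the standard minimal choice.
   Parameters: `Tm` (K), `dH` (kcal/mol, > 0).
3. **The ligand stabilizes only the folded state**, at fixed free
   concentration `[M]` (no depletion).
4. **Observable**: the printed native fraction
   `S_n = (1 + [M]/Kd + Ku)^-1` *decreases* with `[M]`; since the
   complex is also folded, the CD-visible folded fraction is modelled as
   `(1 + [M]/Kd)·S_n`, which increases with `[M]` and reproduces the
   rightward melt shifts the model exists to explain. Both quantities are
   exposed (`native_fraction()` returns `S_n` and `folded`); the printed
   formula is implemented verbatim.

Fitting is deliberately boring and deterministic: linear baselines over
the first/last 15 % of the temperature grid (defaults; the grid spans
298–363 K, the conventional protein CD melt range), normalization clipped
to [−0.1, 1.1]; `(Tm, dH)` by a fixed grid (Tm at 1 K steps, dH 20–200 at
10 kcal/mol steps) plus Nelder–Mead refinement; `Kd` by 1-D optimization
of `log10(Kd)` on [−9, −1]. A complex curve statistically
indistinguishable from the reference (negligible residual improvement,
optimum pinned at the weak end, or predicted stabilization below 0.02)
is reported as a *lower bound* on Kd rather than a value — weak binders
genuinely are unidentifiable in this assay.

The model yields a relative affinity ranking only. It cannot deliver
absolute ΔH/ΔS of binding (partially folded states and
complex-dissociation coupling are outside the two-state closure), and the
reported Kd is the weakest affinity compatible with the data under these
assumptions.

Parameter-recovery conditions in the tests mirror the assay conditions the
model is used under: reference Tm 332 K, dH 80 kcal/mol, protein 2 µM,
mimetic 4.5 µM, Gaussian noise sd 0.01 on the normalized signal, true Kd
spanning 0.05–30 µM.

## 6. Crystal-structure reproduction and limitations

Three test blocks reproduce published geometry from crystal structures:
the ≤ 12 Å pairwise proximity of the three receptor functionalities, the
worked query's seven helical motif matches at their published residue
numbers, and the ~800 Å² (±15 %) buried cytokine–receptor interface.
These require the corresponding PDB entries on disk
(`scripts/fetch_structures.R`; the package performs no network access
itself) and fail with an explanatory message when the files are absent.
For the interface area, the cytokine side is taken as all non-receptor
chains: the receptor-facing "domain" of this domain-swapped dimer is
assembled from both chains, and atoms remote from the interface cancel in
the SASA difference.

Known limitations: no structure superposition or secondary-structure
assignment (hit classification as "helical" remains a downstream,
by-inspection step); angle constraints on single residues depend on the
N→C convention above; pattern matching is per-model (no cross-model NMR
ensembles); the planted-motif generator does not plant angle constraints;
and corpus-scale match counts depend on the user's snapshot and
redundancy reduction of the structure set, so no historical corpus-wide
count is asserted anywhere in the package.
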