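---
title: "Ligand restraint generation, validation and verification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand restraint generation, validation and verification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligrest)
```

## The model

A restraint dictionary for a chemical component is a set of target values
with uncertainties for five classes of internal coordinate: bond lengths,
valence angles, torsion angles, planar groups and chiral volumes. In
refinement these act as a prior: the contribution of each restraint to the
target function is the squared deviation from its ideal value weighted by
1/esd². `ligrest` turns a component with trusted Cartesian coordinates
into such a dictionary, and provides the two independent checks a library
builder needs: statistical validation of the geometry against reference
distributions, and a mechanical check that the restraints actually hold
the geometry they were derived from.

The package assumes its input coordinates are already the "best available"
geometry for the component — in library construction that role is played
by an external quantum-chemistry minimiser. That engine is out of scope
here by design; the pipeline exposes a `geometry_source` function slot
whose default is the identity (input coordinates accepted as the minimised
geometry), so any engine can be plugged in without changing the contract.

## Perception from the bond graph

Internal coordinates are perceived deterministically from atoms, bonds and
coordinates (`perceive_internal_coordinates()`):

* **Bonds** — every bond in the table.
* **Angles** — every bonded path i–j–k, flanks in name order.
* **Torsions** — one representative quad per central bond, with flanking
  atoms chosen heavy-before-hydrogen then lexicographically so output is
  reproducible across platforms; then additional quads until every
  hydrogen with a four-atom path through it terminates at least one quad.
  The extra quads are what make a riding-hydrogen model workable: a
  hydrogen position is rebuilt from one bond, one angle and one torsion,
  so all three must exist for every H.
* **Planes** — connected clusters of atoms carrying a double or aromatic
  bond, plus their direct substituents; a candidate group is accepted when
  the largest out-of-best-fit-plane height is at most `plane_tolerance`
  (0.02 Å default — roughly the coordinate noise of a well-refined
  structure, configurable).
* **Chiral centres** — atoms with four substituent branches that are
  pairwise distinct under a (depth, element)-multiset branch signature.
  Chirality is stored as the signed volume (Å³) of the three
  highest-priority neighbour vectors rather than as an R/S label, because
  the signed volume is what the restraint formalism penalises. The
  signature resolves every case in small ligands; exotic symmetric cages
  could in principle fool it, a known limitation.

## Restraint values

Ideals are *measured from the input geometry*, which gives the central
invariant of the package: the input geometry is a zero-residual point of
its own restraints (asserted to 1e−8 in the tests). E.s.d.s are assigned
as:

| class | with reference match | default | why |
|---|---|---|---|
| bond | 2 × reference s.d. | 0.02 Å | raw small-molecule spreads are too tight as refinement weights at macromolecular resolutions; doubling them is established practice |
| angle | 2 × reference s.d. | 3.0° | same |
| torsion (periodic) | — | 30° | torsions are soft; reference tables cover bonds/angles only |
| torsion (discrete) | — | 15° | discrete wells are asserted more confidently than periodic ones |
| plane | — | 0.02 Å | matches the planarity detection tolerance |
| chiral | — | 0.2 Å³ | conventional magnitude |

A reference entry whose doubled s.d. would not be positive falls back to
the class default — restraint e.s.d.s must be strictly positive, and the
validation floors (below) are a property of validation, not of generation.

Torsion periodicity comes from the hybridisation of the central-bond
atoms, derived from bond orders: sp3–sp3 → 3, sp2–sp2 → 2, anything else
→ 1. When the caller supplies a conformer list for a torsion (keyed by
central bond or full atom path), the restraint becomes *discrete*: its
ideal is a list of allowed values rather than a period. This is needed
whenever the real well set is not periodic — a tryptophan-like chi2 sits
at 0°, 90° and −90° but not 180°, which no periodicity integer can
express. The monomer-library CIF dialect has no list column, so discrete
restraints serialise as one row per value with ids suffixed `_alt1`,
`_alt2`, … and period 1; the reader folds them back.

## Eligibility, termini and protonation

The pipeline filters components in a fixed order: single-atom entities,
entities containing a metal (any element outside a fixed non-metal allow
list — dictionaries never enumerate the metals, so the allow list is the
documented choice), standard residues, obsolete entries, and the unknown
placeholders UNX/UNL. Polymerisable amino-acid entities get the terminus
atoms H2, OXT and HXT removed from the emitted restraints — linked into a
chain those atoms do not exist — by exact set-difference: a restraint is
dropped iff it references one of the three names, and the operation is
idempotent.

Deprotonated carboxylates are detected from the graph (carbon with a
double-bonded oxygen and a singly-bonded, singly-connected O⁻); each site
can receive a proton with standard carboxylic-acid geometry (O–H 0.98 Å,
C–O–H 106°, H anti-periplanar to the carbonyl oxygen, in the carboxyl
plane). The default policy emits a single extra variant with *all* acid
sites protonated — one low-pH form per component — because per-site
dictionaries multiply storage without a clear consumer;
`policy = "combinatorial"` provides the power set when needed.

## Validation

Every measured bond and angle is keyed by a canonical typed tuple —
element + degree + aromatic flag per atom, pair sorted for bonds, flanks
sorted around a fixed apex for angles. Proprietary fragment-based typing
cannot be reproduced, so this documented, deterministic scheme stands in
for it; its coarseness is visible (it cannot separate metrics that differ
only beyond one bond), and metrics without a reference entry are skipped
but reported as a coverage fraction rather than silently dropped.

Scores are `z = (observed − ideal)/sd` after flooring the s.d. at 0.005 Å
(bonds) or 0.75° (angles): reference entries backed by one or two
observations can have vanishing spread, and the floors — roughly half a
typical spread — let such geometries be judged at all. Classification uses
the maximum |Z| with strict thresholds: < 2 *perfect*, < 4 *grand*, < 6
*ok*, else fail. Two modifiers: a geometry that needed a floor must still
pass (< 6), and is then designated *ok (reasonable std)* regardless of the
tier its Z-score alone would earn — the floored s.d. is ad hoc, so the
result should not advertise a better tier; and a validation restricted to
side-chain atoms appends *(side chain)*. The side chain of a
non-standard amino acid is everything outside the backbone set
{N, CA, C, O, OXT, H, H2, HA, HXT}; the r.m.s.Z is reported alongside but
does not drive the classification.

## Minimisation

The verification minimiser is intentionally simple. The target is

E = Σ((d−d₀)/esd)² + Σ((θ−θ₀)/esd)² + Σ(Δτ/esd)² + Σ(h/esd)² +
Σ((V−V₀)/esd)² + w·Σ max(0, r₀−r)²

where Δτ is the wrapped deviation to the nearest periodic well or discrete
ideal, h is the height above the instantaneous best-fit plane of the
group, V the signed chiral volume, and the last sum runs over nonbonded
pairs more than three bonds apart (or in different fragments) with
r₀ = 0.9 × the sum of van der Waals radii — a purely repulsive wall, no
attraction. Gradients are analytic throughout and verified against central
differences to 1e−5 in the tests; the best-fit plane contributes no
indirect gradient because the plane itself minimises the summed squared
heights (envelope argument — exact because the per-atom plane e.s.d. is
uniform within a group). Descent is quasi-Newton (L-BFGS-B) with
convergence declared when the gradient infinity-norm drops below `gtol`
(1e−4 default, max 500 iterations); the procedure is deterministic, and
randomness enters only through the explicit, seeded coordinate
perturbation helper.

The headline check is the fixed point: restraints generated from an ideal
geometry, minimised starting at that geometry, must give an r.m.s.d. to
start (rigid motion removed by Kabsch superposition) below 0.01 Å. At a
zero-residual, clash-free start this is immediate; the test is sensitive
exactly when something is wrong — an ill-formed gradient, a discrete well
list missing the measured conformer, a nonbonded contact at the ideal
geometry.

## What the fixtures emulate — and what they do not

The six generated components (`ethane`, `acetate`, `benzene`,
`trp_sidechain`, `dipeptide_like`, `dicarboxylate`) are built from
standard values — C–C 1.54/1.52 Å, C=O 1.23 Å, delocalised carboxylate
C–O 1.25 Å, C–OH 1.31 Å, aromatic C–C 1.39 Å, C–H 1.09 Å, N–H 1.01 Å,
O–H 0.98 Å, tetrahedral 109.47°, trigonal 120° — with exact torsional
placement, full hydrogens and formal charges. They cover each code path:
a rotatable bond, a charged protonatable group, an aromatic plane, a
discrete-torsion branch point, a polymerisable entity with termini and a
chiral centre, and a two-site acid. Reference tables built from them
(`make_reference_table()`) key measured means by the same typing scheme,
so self-validation is exactly Z = 0.

They are *not* realistic data: coordinates are noise-free, conformers are
single, aromatic bond orders are given rather than perceived, and the
reference tables have user-chosen spreads (defaults 0.01 Å / 1.5° —
about twice the floors, matching the convention that the floors are half
a normal spread). Passing tests therefore demonstrate the correctness of
the machinery — measurement, typing, scoring, serialisation,
minimisation — not the empirical quality of any real dictionary entry,
which depends on the external geometry source and reference data that are
out of scope.

## Numerical choices and degenerate inputs

* Dihedrals use the right-handed IUPAC convention on (−180°, 180°];
  collinear triples raise a degenerate-geometry error rather than return
  an arbitrary value. Torsion deviations wrap to the same interval, so a
  well at 180° is 5° from an observation at −175°.
* Kabsch superposition uses the SVD sign correction that excludes
  reflections (det = +1 always).
* Angle gradients guard sin θ away from zero (1e−12) at exactly linear
  angles; the energy remains finite and descent continues.
* CIF numeric fields are written with nine significant digits: one
  write→read→write cycle is byte-identical, and read(write(x)) = x to
  1e−8.
* The problem sizes throughout (≤ 15 atoms per fixture, six fixtures) keep
  the full suite fast while covering every term type; the brute-force
  superposition oracle in the tests uses a coarse Euler grid, a
  0.1°-resolution local grid and a simplex polish, independent of the SVD
  path it checks.

## Known limitations

* Aromatic bond orders must be supplied; nothing perceives aromaticity
  from SMILES or geometry. Tautomers are not enumerated, and phosphate
  chemistry gets no special handling.
* The atom typing is coarser than fragment-based reference systems;
  validation coverage depends on the reference table supplied.
* Metal-containing components are filtered out, not restrained.
* The minimiser is a verification tool, not a refinement engine: no
  crystallographic targets, no ADPs, no riding-hydrogen regeneration
  during descent.
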