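# ligrest

Geometry restraints for small-molecule ligands and non-standard residues:
generation from a validated 3D geometry, Z-score validation against
reference bond/angle distributions, and verification by restrained
re-minimisation.

## The problem

Macromolecular refinement at typical resolutions cannot determine ligand
geometry from the data alone; it leans on *restraints* — ideal values with
estimated standard deviations (e.s.d.s) for bonds, valence angles,
torsions, planes and chiral volumes — as prior chemical knowledge. Building
a trustworthy restraint dictionary for an arbitrary component involves
three recurring tasks, and `ligrest` implements each behind a tidy,
pipe-friendly API:

1. **Generation.** Given a Chemical Component Dictionary (CCD) style entry
   with coordinates, perceive the internal coordinates from the bond graph
   and measure every ideal value from the geometry, so that the input is by
   construction a zero-residual point of its own restraints. E.s.d.s come
   from a reference table when a typed entry matches (doubled, since raw
   small-molecule spreads are too tight for macromolecular work:
   `esd = 2 × sd`), otherwise from documented defaults. Torsions are
   periodic with the period inferred from the central-bond hybridisation
   (sp3–sp3 → 3, sp2–sp2 → 2, else 1) — or *discrete*, listing explicit
   ideal values, when a well set is not periodic: the classic case is a
   tryptophan-like chi2 that occupies 0°, 90° and −90° but never 180°.
   Hydrogen restraints are complete (each H gets a bond, an angle and a
   torsion) so riding-hydrogen models can reposition every H. Carboxylate
   protonation variants are enumerated for low-pH/neutron work, and the
   polymerisation-terminus atoms H2/OXT/HXT are trimmed from amino-acid
   entities.

2. **Validation.** Each measured bond/angle with a reference entry gets a
   Z-score, `z = (observed − ideal)/sd`, with conservative s.d. floors
   (0.005 Å for bonds, 0.75° for angles) rescuing entries whose reference
   spread is degenerate. The geometry is classified from max |Z| with
   strict thresholds: < 2 *perfect*, < 4 *grand*, < 6 *ok*, else fail;
   floored-but-passing geometries are designated *ok (reasonable std)*,
   and side-chain-restricted validations carry a *(side chain)* modifier.

3. **Verification.** A restrained quasi-Newton minimiser (analytic
   gradients, repulsive-only nonbonded term) checks the fixed-point
   property: restraints generated from an ideal geometry, minimised from
   that geometry, must stay put (r.m.s.d. to start below 0.01 Å, with
   rigid motion removed by Kabsch superposition).

Everything runs on synthetic fixtures (`make_fixture()`), so no downloads
or licensed lookups are needed.

## Worked example

```r
library(ligrest)

act <- make_fixture("acetate")
act
#> <chemical_component> ACT (acetate)
#>   type: non-polymer | 7 atoms, 6 bonds | net charge -1
#>   smiles: CC(=O)[O-]

ref <- make_reference_table(act, sd_bond = 0.011)
r <- generate_restraints(act, reference = ref)
r
#> <geometry_restraints> ACT (neutral variant)
#>   6 bonds, 9 angles, 3 torsions (0 discrete), 1 planes, 0 chirals over 7 atoms

head(tidy(r), 4)
#> # A tibble: 4 x 7
#>   class id    atoms  ideal   esd mode  period
#> 1 bond  NA    C1-C2   1.52 0.022 NA        NA
#> 2 bond  NA    C1-O1   1.25 0.022 NA        NA
#> 3 bond  NA    C1-O2   1.25 0.022 NA        NA
#> 4 bond  NA    C2-H21  1.09 0.022 NA        NA
```

The bond e.s.d.s are exactly twice the reference s.d. (0.022 = 2 × 0.011).
Validating the geometry against its own reference table is the
sanity-check case — every Z-score is zero and the designation is the top
tier:

```r
glance(validate_geometry(act, make_reference_table(act)))
#> # A tibble: 1 x 8
#>   n_metrics coverage max_abs_z  rms_z classification reasonable_std ...
#> 1        15        1         0      0 perfect        FALSE
```

Perturb the coordinates and the minimiser walks back to the ideal
geometry; start *at* the ideal geometry and it does not move:

```r
res <- minimize_geometry(perturb_coordinates(act, 0.05, 7), r, energy_model(act))
res
#> <minimization_result> converged after 60 iterations: residual 2.8e-12,
#>   r.m.s.d. to start 0.0884 A

run_pipeline(list(act), make_reference_table(act))[
  , c("id", "eligible", "designation", "n_variants", "rmsd_fixed_point")]
#> # A tibble: 1 x 5
#>   id    eligible designation n_variants rmsd_fixed_point
#> 1 ACT   TRUE     perfect              2                0
```

The pipeline row shows acetate passing the eligibility filters, earning a
*perfect* designation, producing two protonation variants (acetate and
acetic acid) and keeping its geometry fixed under re-minimisation.

A thin command-line front end over the same functions lives at
`inst/cli/ligrest.R` (subcommands `fixtures`, `validate`, `minimize`,
`pipeline`).

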