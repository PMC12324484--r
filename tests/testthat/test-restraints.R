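fixture_names <- c("ethane", "acetate", "benzene", "trp_sidechain",
                   "dipeptide_like", "dicarboxylate")

test_that("restraint ideals are the measured values and e.s.d.s default correctly", {
  comp <- make_fixture("ethane")
  r <- generate_restraints(comp)
  co <- component_coordinates(comp)
  expect_equal(
    r$bonds$ideal,
    purrr::map2_dbl(r$bonds$atom_1, r$bonds$atom_2,
                    ~ bond_length(co[.x, ], co[.y, ])))
  expect_true(all(r$bonds$esd == 0.02))
  expect_true(all(r$angles$esd == 3.0))
  # the representative H-C-C-H torsion about an sp3-sp3 bond has period 3
  expect_true(all(r$torsions$mode == "periodic"))
  expect_true(all(r$torsions$period == 3L))
  expect_true(all(r$torsions$esd == 30))
})

test_that("a matching reference entry sets the e.s.d. to twice its s.d.", {
  comp <- make_fixture("acetate")
  ref <- make_reference_table(comp, sd_bond = 0.011, sd_angle = 1.2)
  r <- generate_restraints(comp, reference = ref)
  expect_true(all(abs(r$bonds$esd - 0.022) < 1e-12))
  expect_true(all(abs(r$angles$esd - 2.4) < 1e-12))
  # an sd-zero reference entry cannot produce a non-positive e.s.d.
  ref0 <- make_reference_table(comp, zero_sd_keys = ref$type_key)
  r0 <- generate_restraints(comp, reference = ref0)
  expect_true(all(r0$bonds$esd == 0.02))
  expect_true(all(r0$bonds$esd > 0))
})

test_that("caller-supplied conformers make the chi2-like torsion discrete", {
  comp <- make_fixture("trp_sidechain")
  r <- generate_restraints(comp, conformers = list("CB-CG" = c(0, 90, -90)))
  chi2 <- r$torsions[r$torsions$atom_1 == "CA" & r$torsions$atom_4 == "CD1", ]
  expect_equal(nrow(chi2), 1L)
  expect_equal(chi2$mode, "discrete")
  expect_equal(chi2$ideal_list[[1]], c(0, 90, -90))
  expect_equal(chi2$esd, 15)
  expect_true(is.na(chi2$period))
  # sp2-sp2 central bonds get period 2, mixed bonds period 1
  r2 <- generate_restraints(make_fixture("benzene"))
  ring <- r2$torsions[!grepl("H", r2$torsions$atom_2), ]
  expect_true(all(ring$period == 2L))
  # sp2-sp3 central bond (CG-CD2) gets period 1
  mixed <- r$torsions[(r$torsions$atom_2 %in% c("CG", "CD2")) &
                        (r$torsions$atom_3 %in% c("CG", "CD2")), ]
  expect_gt(nrow(mixed), 0)
  expect_true(all(mixed$period == 1L))
  expect_error(
    generate_restraints(comp, conformers = list("CB-CG" = c(0, 360))),
    "duplicate")
})

test_that("the input geometry is a zero-residual point of its own restraints", {
  for (nm in fixture_names) {
    comp <- make_fixture(nm)
    conf <- if (nm == "trp_sidechain") list("CB-CG" = c(0, 90, -90)) else NULL
    r <- generate_restraints(comp, conformers = conf)
    model <- energy_model(comp, nonbonded_weight = 0)
    e <- residual_energy(component_coordinates(comp), r, model)
    expect_lt(e$energy, 1e-8)
  }
})

test_that("every hydrogen is restrained for riding positioning", {
  for (nm in fixture_names) {
    comp <- make_fixture(nm)
    r <- generate_restraints(comp)
    hs <- comp$atoms$atom[comp$atoms$element == "H"]
    expect_true(all(hs %in% c(r$bonds$atom_1, r$bonds$atom_2)), label = nm)
    expect_true(all(hs %in% c(r$angles$atom_1, r$angles$atom_3)), label = nm)
    expect_true(all(hs %in% c(r$torsions$atom_1, r$torsions$atom_4)), label = nm)
  }
})

test_that("terminus trimming removes exactly the H2/OXT/HXT restraints", {
  comp <- make_fixture("dipeptide_like")
  r <- generate_restraints(comp)
  trimmed <- trim_polymer_termini(r, comp)
  drop <- c("H2", "OXT", "HXT")
  expect_length(intersect(trimmed$atoms, drop), 0)
  named <- function(rr) {
    c(paste("b", rr$bonds$atom_1, rr$bonds$atom_2),
      paste("a", rr$angles$atom_1, rr$angles$atom_2, rr$angles$atom_3),
      paste("t", rr$torsions$atom_1, rr$torsions$atom_2, rr$torsions$atom_3,
            rr$torsions$atom_4),
      paste("p", rr$planes$plane_id, rr$planes$atom),
      paste("c", rr$chirals$centre, rr$chirals$neighbour_1,
            rr$chirals$neighbour_2, rr$chirals$neighbour_3))
  }
  removed <- setdiff(named(r), named(trimmed))
  expect_true(all(grepl("H2|OXT|HXT", removed)))
  expect_length(setdiff(named(trimmed), named(r)), 0)
  touches_sets <- vapply(strsplit(named(r), " "), function(x)
    any(x[-1] %in% drop), logical(1))
  expect_equal(sort(removed), sort(named(r)[touches_sets]))
  # bond count drops by the terminus atoms' degree
  deg <- sum(comp$bonds$atom_1 %in% drop | comp$bonds$atom_2 %in% drop)
  expect_equal(nrow(r$bonds) - nrow(trimmed$bonds), deg)
  # idempotent, and a no-op on non-polymer components
  expect_restraints_equal(trim_polymer_termini(trimmed, comp), trimmed)
  act <- make_fixture("acetate")
  ra <- generate_restraints(act)
  expect_restraints_equal(trim_polymer_termini(ra, act), ra)
})

test_that("protonation variants add a proton per carboxylate site", {
  act <- make_fixture("acetate")
  vars <- enumerate_protonation_variants(act)
  expect_length(vars, 2L)
  expect_equal(vars[[1]]$variant, "neutral")
  prot <- vars[[2]]
  expect_equal(prot$variant, "protonated")
  expect_equal(nrow(prot$atoms), nrow(act$atoms) + 1L)
  expect_equal(sum(prot$atoms$charge), 0L)
  expect_true("HO2" %in% prot$atoms$atom)
  co <- component_coordinates(prot)
  expect_equal(bond_length(co["O2", ], co["HO2", ]), 0.98, tolerance = 1e-9)
  expect_equal(bond_angle(co["C1", ], co["O2", ], co["HO2", ]), 106,
               tolerance = 1e-9)
  # anti-periplanar to the carbonyl oxygen, in the carboxyl plane
  expect_equal(abs(dihedral(co["O1", ], co["C1", ], co["O2", ], co["HO2", ])),
               180, tolerance = 1e-9)

  expect_length(enumerate_protonation_variants(make_fixture("ethane")), 1L)

  dcx <- make_fixture("dicarboxylate")
  expect_length(enumerate_protonation_variants(dcx), 2L)
  both <- enumerate_protonation_variants(dcx)[[2]]
  expect_equal(sum(both$atoms$element == "H"), 4L)
  expect_length(enumerate_protonation_variants(dcx, policy = "combinatorial"), 4L)
})

test_that("restraint CIF writing round-trips, including discrete torsions", {
  for (nm in fixture_names) {
    comp <- make_fixture(nm)
    conf <- if (nm == "trp_sidechain") list("CB-CG" = c(0, 90, -90)) else NULL
    r <- generate_restraints(comp, conformers = conf)
    doc <- write_restraints_cif(r)
    expect_restraints_equal(read_restraints_cif(doc), r)
  }
  # the dialect carries the expected loops
  doc <- write_restraints_cif(generate_restraints(make_fixture("acetate")))
  for (tag in c("_chem_comp_bond", "_chem_comp_angle", "_chem_comp_tor",
                "_chem_comp_plane_atom")) {
    expect_true(grepl(tag, doc, fixed = TRUE), label = tag)
  }
})

test_that("discrete torsions serialise as _alt rows with period 1", {
  comp <- make_fixture("trp_sidechain")
  r <- generate_restraints(comp, conformers = list("CB-CG" = c(0, 90, -90)))
  doc <- write_restraints_cif(r)
  expect_true(grepl("tor_CB_CG_alt1", doc))
  expect_true(grepl("tor_CB_CG_alt3", doc))
  back <- read_restraints_cif(doc)
  tor <- back$torsions[back$torsions$mode == "discrete", ]
  expect_equal(tor$ideal_list[[1]], c(0, 90, -90))
})

test_that("a 5-character component id survives the restraint round-trip", {
  comp <- make_fixture("acetate")
  comp$id <- "A1B2C"
  r <- generate_restraints(comp)
  expect_equal(read_restraints_cif(write_restraints_cif(r))$component_id,
               "A1B2C")
})

test_that("emitted e.s.d. values are strictly positive and write refuses others", {
  for (nm in fixture_names) {
    r <- generate_restraints(make_fixture(nm))
    expect_true(all(c(r$bonds$esd, r$angles$esd, r$torsions$esd,
                      r$planes$esd, r$chirals$esd) > 0), label = nm)
  }
  r <- generate_restraints(make_fixture("ethane"))
  r$bonds$esd[1] <- 0
  expect_error(write_restraints_cif(r), "positive")
})

test_that("reference tables round-trip through CSV", {
  tab <- make_reference_table(purrr::map(fixture_names, make_fixture))
  path <- withr::local_tempfile(fileext = ".csv")
  write_reference_table(tab, path)
  back <- read_reference_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
  # shared keys accumulate observation counts
  tab2 <- make_reference_table(list(make_fixture("ethane"),
                                    make_fixture("trp_sidechain")))
  cc <- tab2[tab2$kind == "bond" & tab2$type_key == "C4-C4", ]
  expect_gte(cc$n_obs, 2L)
})
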