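test_that("a minimal two-atom CIF parses to the expected component", {
  txt <- c(
    "data_XYZ",
    "_chem_comp.id XYZ",
    "_chem_comp.name 'carbon monoxide toy'",
    "_chem_comp.type NON-POLYMER",
    "_chem_comp.pdbx_release_status REL",
    "loop_",
    "_chem_comp_atom.atom_id",
    "_chem_comp_atom.type_symbol",
    "_chem_comp_atom.charge",
    "_chem_comp_atom.model_Cartn_x",
    "_chem_comp_atom.model_Cartn_y",
    "_chem_comp_atom.model_Cartn_z",
    "C1 C 0 0.0 0.0 0.0",
    "O1 O 0 0.0 0.0 1.43",
    "loop_",
    "_chem_comp_bond.atom_id_1",
    "_chem_comp_bond.atom_id_2",
    "_chem_comp_bond.value_order",
    "C1 O1 SING")
  comp <- parse_component_cif(txt)
  expect_s3_class(comp, "chemical_component")
  expect_equal(nrow(comp$atoms), 2L)
  expect_equal(nrow(comp$bonds), 1L)
  expect_equal(comp$name, "carbon monoxide toy")
  expect_equal(comp$bonds$order, "single")
  expect_true(has_coordinates(comp))
})

test_that("a bond naming an atom absent from the atom loop is an integrity error", {
  txt <- c(
    "data_BAD",
    "_chem_comp.id BAD",
    "loop_",
    "_chem_comp_atom.atom_id",
    "_chem_comp_atom.type_symbol",
    "C1 C", "O1 O",
    "loop_",
    "_chem_comp_bond.atom_id_1",
    "_chem_comp_bond.atom_id_2",
    "_chem_comp_bond.value_order",
    "C1 XX9 SING")
  expect_error(parse_component_cif(txt), "XX9")
})

test_that("malformed CIF reports the offending construct", {
  expect_error(parse_component_cif("data_A\nloop_\nvalue_without_tags"),
               "loop_")
  expect_error(parse_component_cif("_tag value"), "data_")
  expect_error(
    parse_component_cif("data_A\nloop_\n_x.a\n_x.b\nv1 v2 v3"),
    "row count")
})

test_that("write then parse is the identity on every fixture", {
  for (nm in c("ethane", "acetate", "benzene", "trp_sidechain",
               "dipeptide_like", "dicarboxylate")) {
    comp <- make_fixture(nm)
    back <- parse_component_cif(write_component_cif(comp))
    expect_component_equal(back, comp)
  }
})

test_that("components without coordinates round-trip without Cartesian columns", {
  comp <- make_fixture("ethane")
  comp$atoms$x <- comp$atoms$y <- comp$atoms$z <- NA_real_
  doc <- write_component_cif(comp)
  expect_false(grepl("model_Cartn", doc))
  back <- parse_component_cif(doc)
  expect_false(has_coordinates(back))
  expect_equal(back$atoms$atom, comp$atoms$atom)
})

test_that("obsolete status, parent id and 5-character ids survive a round-trip", {
  comp <- make_fixture("acetate")
  comp$id <- "A1B2C"
  comp$obsolete <- TRUE
  comp$parent_id <- "ALA"
  back <- parse_component_cif(write_component_cif(comp))
  expect_equal(back$id, "A1B2C")
  expect_true(back$obsolete)
  expect_equal(back$parent_id, "ALA")
})

test_that("eligibility filters match the library-construction rules", {
  mg <- chemical_component(
    "MG", atoms = tibble::tibble(atom = "MG", element = "Mg", charge = 2L),
    bonds = tibble::tibble())
  expect_equal(assess_eligibility(mg)$reason, "single-atom")
  expect_false(assess_eligibility(mg)$eligible)

  heme_like <- chemical_component(
    "HEX", atoms = tibble::tibble(atom = c("FE", "N1", "N2"),
                                  element = c("Fe", "N", "N"), charge = 0L),
    bonds = tibble::tibble(atom_1 = c("FE", "FE"), atom_2 = c("N1", "N2"),
                           order = "single"))
  expect_equal(assess_eligibility(heme_like)$reason, "contains-metal")

  expect_equal(assess_eligibility(make_fixture("acetate"))$reason, "ok")
  expect_true(assess_eligibility(make_fixture("acetate"))$eligible)

  ala_like <- make_fixture("dipeptide_like")
  expect_equal(assess_eligibility(ala_like, standard_residue_ids = "DPL")$reason,
               "standard-residue")

  obs <- make_fixture("ethane"); obs$obsolete <- TRUE
  expect_equal(assess_eligibility(obs)$reason, "obsolete")

  unl <- make_fixture("ethane"); unl$id <- "UNL"
  expect_equal(assess_eligibility(unl)$reason, "unknown-entity")
})

test_that("eligibility is order-independent of the atom list", {
  comp <- make_fixture("dicarboxylate")
  shuffled <- comp
  ord <- rev(seq_len(nrow(comp$atoms)))
  shuffled$atoms <- comp$atoms[ord, ]
  expect_equal(assess_eligibility(shuffled), assess_eligibility(comp))
})

test_that("component invariants reject bad input", {
  expect_error(chemical_component(
    "TOOLONG1", atoms = tibble::tibble(atom = "C1", element = "C", charge = 0L),
    bonds = tibble::tibble()), "1-5 alphanumeric")
  expect_error(chemical_component(
    "DUP", atoms = tibble::tibble(atom = c("C1", "C1"), element = "C",
                                  charge = 0L),
    bonds = tibble::tibble()), "duplicate atom")
  expect_error(chemical_component(
    "PCO", atoms = tibble::tibble(atom = c("C1", "C2"), element = "C",
                                  charge = 0L, x = c(0, NA), y = 0, z = 0),
    bonds = tibble::tibble()), "all atoms or none")
})
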