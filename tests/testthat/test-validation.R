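test_that("zscore and s.d. floors follow their definitions", {
  expect_equal(zscore(1.54, 1.52, 0.01), 2)
  expect_equal(zscore(120, 120, 1.5), 0)
  expect_equal(zscore(1.50, 1.52, 0.01), -2)
  expect_error(zscore(1, 1, 0), "positive")

  expect_equal(apply_sd_floor(0, "bond"),
               tibble::tibble(sd_effective = 0.005, floored = TRUE))
  expect_equal(apply_sd_floor(0.5, "angle"),
               tibble::tibble(sd_effective = 0.75, floored = TRUE))
  expect_equal(apply_sd_floor(0.02, "bond"),
               tibble::tibble(sd_effective = 0.02, floored = FALSE))
})

test_that("classification tiers use strict thresholds", {
  expect_equal(classify(1.9)$classification, "perfect")
  expect_equal(classify(2.0)$classification, "grand")
  expect_equal(classify(3.99)$classification, "grand")
  expect_equal(classify(4.0)$classification, "ok")
  expect_equal(classify(5.99)$classification, "ok")
  expect_equal(classify(6.0)$classification, "fail")
  # floored s.d.s relabel any passing tier as ok (reasonable std)
  cl <- classify(1.0, floored_any = TRUE)
  expect_equal(cl$classification, "ok")
  expect_true(cl$reasonable_std)
  expect_equal(cl$designation, "ok (reasonable std)")
  expect_equal(classify(7, floored_any = TRUE)$classification, "fail")
  # side-chain-restricted validations carry the modifier
  expect_equal(classify(1.0, side_chain_only = TRUE)$designation,
               "perfect (side chain)")
})

test_that("classification is monotone in max |Z|", {
  tiers <- c(perfect = 1L, grand = 2L, ok = 3L, fail = 4L)
  zs <- seq(0, 8, by = 0.25)
  cls <- tiers[vapply(zs, function(z) classify(z)$classification, character(1))]
  expect_true(all(diff(cls) >= 0))
})

test_that("self-validation is perfect with zero Z for every fixture", {
  for (nm in c("ethane", "acetate", "benzene", "trp_sidechain",
               "dipeptide_like", "dicarboxylate")) {
    comp <- make_fixture(nm)
    rep <- validate_geometry(comp, make_reference_table(comp))
    expect_equal(rep$max_abs_z, 0, tolerance = 1e-9, label = nm)
    expect_equal(rep$classification, "perfect", label = nm)
    expect_equal(rep$coverage, 1)
  }
})

test_that("a reference ideal shifted by 3 s.d. moves the geometry to grand", {
  comp <- make_fixture("acetate")
  ref <- make_reference_table(comp, sd_bond = 0.01)
  # shift one uniquely-keyed bond ideal (methyl C-H) by exactly 3 s.d.
  i <- which(ref$kind == "bond" & ref$type_key == "C4-H1")
  ref$ideal[i] <- ref$ideal[i] + 3 * ref$sd[i]
  rep <- validate_geometry(comp, ref)
  expect_equal(rep$max_abs_z, 3, tolerance = 1e-9)
  expect_equal(rep$classification, "grand")
  expect_equal(rep$designation, "grand")
})

test_that("sd-zero reference entries are floored and flagged reasonable std", {
  comp <- make_fixture("acetate")
  ref <- make_reference_table(comp, zero_sd_keys = "C4-H1")
  rep <- validate_geometry(comp, ref)
  floored <- rep$records[rep$records$floored, ]
  expect_gt(nrow(floored), 0)
  expect_true(all(floored$sd_effective == 0.005))
  expect_true(rep$reasonable_std)
  expect_equal(rep$designation, "ok (reasonable std)")
  # floors are never undercut
  expect_true(all(
    rep$records$sd_effective >=
      ifelse(rep$records$kind == "bond", 0.005, 0.75)))
})

test_that("rms_z never exceeds max |Z|, with equality for a single record", {
  comp <- make_fixture("dicarboxylate")
  ref <- make_reference_table(comp)
  ref$ideal <- ref$ideal + c(0.5, -1, 1.5)[seq_along(ref$ideal) %% 3 + 1] * ref$sd
  rep <- validate_geometry(comp, ref)
  expect_lte(rep$rms_z, rep$max_abs_z)
  toy <- two_atom_toy(1.44)
  rep1 <- validate_geometry(toy, make_reference_table(two_atom_toy(1.43)))
  expect_equal(nrow(rep1$records), 1L)
  expect_equal(rep1$rms_z, rep1$max_abs_z)
})

test_that("side-chain restriction limits the metrics and flags the report", {
  comp <- make_fixture("dipeptide_like")
  ref <- make_reference_table(comp)
  full <- validate_geometry(comp, ref)
  side <- validate_geometry(comp, ref, restrict_to = side_chain_atoms(comp))
  expect_true(side$side_chain)
  expect_lt(nrow(side$records), nrow(full$records))
  expect_match(side$designation, "(side chain)", fixed = TRUE)
  sc <- side_chain_atoms(comp)
  expect_true(all(vapply(strsplit(side$records$atoms, "-"),
                         function(a) all(a %in% sc), logical(1))))
})

test_that("zero reference coverage fails with a no-coverage flag", {
  toy <- two_atom_toy(1.43)
  ref <- make_reference_table(make_fixture("benzene"))
  rep <- validate_geometry(toy, ref)
  expect_true(rep$no_coverage)
  expect_equal(rep$classification, "fail")
  expect_equal(rep$coverage, 0)
})

test_that("tidiers expose the report as tables", {
  comp <- make_fixture("acetate")
  rep <- validate_geometry(comp, make_reference_table(comp))
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("kind", "observed", "ideal", "z") %in% names(td)))
  gl <- glance(rep)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$classification, "perfect")
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})
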