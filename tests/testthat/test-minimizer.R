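fixture_names <- c("ethane", "acetate", "benzene", "trp_sidechain",
                   "dipeptide_like", "dicarboxylate")

test_that("torsion deviation finds the nearest periodic well or discrete ideal", {
  per3 <- list(mode = "periodic", ideal = 60, period = 3L)
  expect_equal(torsion_deviation(65, per3), 5)
  # wells at 60, 180, -60: -175 is 5 away from 180 across the seam
  expect_equal(torsion_deviation(-175, per3), 5)
  disc <- list(mode = "discrete", ideal_list = c(0, 90, -90))
  expect_equal(torsion_deviation(180, disc), 90)
  expect_equal(torsion_deviation(-95, disc), 5)
  # enumeration oracle over random cases
  set.seed(33)
  for (k in 1:50) {
    obs <- stats::runif(1, -180, 180)
    p <- sample(1:6, 1)
    ideal <- stats::runif(1, -180, 180)
    wells <- ideal + (seq_len(p) - 1) * 360 / p
    expect_equal(
      torsion_deviation(obs, list(mode = "periodic", ideal = ideal, period = p)),
      torsion_deviation_enum(obs, wells), tolerance = 1e-9)
  }
})

test_that("single-term energies match hand arithmetic", {
  toy <- two_atom_toy(1.52)
  r <- generate_restraints(toy)
  r$bonds$ideal <- 1.5
  r$bonds$esd <- 0.02
  model <- energy_model(toy)
  e <- residual_energy(component_coordinates(toy), r, model)
  expect_equal(e$energy, 1.0, tolerance = 1e-12)
  expect_error(residual_energy(matrix(NaN, 2, 3,
                                      dimnames = list(c("C1", "O1"), NULL)),
                               r, model), "non-finite")
})

test_that("analytic gradients match central differences on every fixture", {
  for (nm in fixture_names) {
    comp <- make_fixture(nm)
    conf <- if (nm == "trp_sidechain") list("CB-CG" = c(0, 90, -90)) else NULL
    r <- generate_restraints(comp, conformers = conf)
    model <- energy_model(comp, nonbonded_weight = 25)
    co <- perturb_coordinates(comp, 0.05, 42)
    g <- residual_energy(co, r, model)$gradient
    expect_lt(max(abs(g - fd_gradient(co, r, model))), 1e-5)
  }
})

test_that("restraints generated from the ideal geometry keep it fixed", {
  for (nm in fixture_names) {
    comp <- make_fixture(nm)
    r <- generate_restraints(comp)
    res <- minimize_geometry(component_coordinates(comp), r, energy_model(comp))
    expect_true(res$converged, label = nm)
    expect_lt(res$rmsd_to_start, 0.01)
  }
})

test_that("minimisation recovers a perturbed geometry", {
  comp <- make_fixture("acetate")
  r <- generate_restraints(comp)
  model <- energy_model(comp)
  start <- perturb_coordinates(comp, 0.05, 17)
  e_start <- residual_energy(start, r, model)$energy
  res <- minimize_geometry(start, r, model)
  expect_true(res$converged)
  expect_lt(res$final_residual, e_start)
  rmsd_to_ideal <- superpose_rmsd(component_coordinates(comp),
                                  res$final_coordinates)$rmsd
  expect_lt(rmsd_to_ideal, 0.05)
})

test_that("zero restraints converge immediately with no motion", {
  comp <- make_fixture("ethane")
  r <- generate_restraints(comp)
  for (f in c("bonds", "angles", "torsions", "planes", "chirals")) {
    r[[f]] <- r[[f]][0, ]
  }
  model <- energy_model(comp, nonbonded_weight = 0)
  model$nonbonded_pairs <- model$nonbonded_pairs[0, ]
  res <- minimize_geometry(component_coordinates(comp), r, model)
  expect_true(res$converged)
  expect_equal(res$iterations, 0L)
  expect_equal(res$rmsd_to_start, 0)
})

test_that("energy is non-negative and zero only at the ideal point", {
  comp <- make_fixture("benzene")
  r <- generate_restraints(comp)
  model <- energy_model(comp)
  co <- component_coordinates(comp)
  expect_equal(residual_energy(co, r, model)$energy, 0, tolerance = 1e-10)
  expect_gt(residual_energy(perturb_coordinates(comp, 0.03, 1), r,
                            model)$energy, 0)
})

test_that("the nonbonded term is repulsive-only and excludes 1-2/1-3/1-4 pairs", {
  comp <- make_fixture("ethane")
  model <- energy_model(comp)
  np <- model$nonbonded_pairs
  # in ethane every pair is within 3 bonds: nothing survives exclusion
  expect_equal(nrow(np), 0L)
  bz <- make_fixture("benzene")
  mb <- energy_model(bz)
  expect_gt(nrow(mb$nonbonded_pairs), 0L)
  # stretching a pair beyond contact distance contributes nothing
  co <- component_coordinates(bz) * 2
  r <- generate_restraints(bz)
  for (f in c("bonds", "angles", "torsions", "planes", "chirals")) r[[f]] <- r[[f]][0, ]
  expect_equal(residual_energy(co, r, mb)$energy, 0)
})

test_that("minimisation result glance is a one-row tibble", {
  comp <- make_fixture("acetate")
  res <- minimize_geometry(component_coordinates(comp),
                           generate_restraints(comp), energy_model(comp))
  gl <- glance(res)
  expect_equal(nrow(gl), 1L)
  expect_true(gl$converged)
})
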