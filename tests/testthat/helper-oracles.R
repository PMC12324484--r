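# Shared helpers: independent oracles and comparison utilities.

# central-difference gradient of the residual energy
fd_gradient <- function(coords, restraints, model, h = 1e-5) {
  g <- coords * 0
  for (i in seq_len(nrow(coords))) {
    for (j in 1:3) {
      cp <- coords; cp[i, j] <- cp[i, j] + h
      cm <- coords; cm[i, j] <- cm[i, j] - h
      g[i, j] <- (residual_energy(cp, restraints, model)$energy -
                    residual_energy(cm, restraints, model)$energy) / (2 * h)
    }
  }
  g
}

euler_rotation <- function(a, b, g) {
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cg <- cos(g); sg <- sin(g)
  rz1 <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
  ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  rz2 <- matrix(c(cg, sg, 0, -sg, cg, 0, 0, 0, 1), 3, 3)
  rz1 %*% ry %*% rz2
}

# direct-search superposition oracle, independent of the SVD route:
# centre both sets, coarse Euler-angle grid, 0.1-degree local grid around
# the best cell, then simplex polish.
rmsd_brute_force <- function(reference, moving) {
  X <- sweep(reference, 2, colMeans(reference))
  Y <- sweep(moving, 2, colMeans(moving))
  n <- nrow(X)
  rmsd_at <- function(p) {
    R <- euler_rotation(p[1], p[2], p[3])
    sqrt(sum((X - Y %*% t(R))^2) / n)
  }
  best <- c(0, 0, 0); best_v <- rmsd_at(best)
  step <- 20 * pi / 180
  for (a in seq(0, 2 * pi - step, by = step)) {
    for (b in seq(0, pi, by = step)) {
      for (g in seq(0, 2 * pi - step, by = step)) {
        v <- rmsd_at(c(a, b, g))
        if (v < best_v) { best_v <- v; best <- c(a, b, g) }
      }
    }
  }
  fine <- 0.1 * pi / 180
  grid <- seq(-10 * fine, 10 * fine, by = fine)
  for (da in grid) for (db in grid) for (dg in grid) {
    v <- rmsd_at(best + c(da, db, dg))
    if (v < best_v) { best_v <- v; best <- best + c(da, db, dg) }
  }
  fit <- stats::optim(best, rmsd_at, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
  min(best_v, fit$value)
}

# minimal torsion deviation by explicit well enumeration over k * 360 / p
torsion_deviation_enum <- function(observed, wells) {
  cands <- abs(ligrest::wrap_angle(observed - wells))
  min(cands)
}

expect_component_equal <- function(a, b) {
  expect_equal(a$id, b$id)
  expect_equal(a$name, b$name)
  expect_equal(a$type, b$type)
  expect_equal(a$smiles, b$smiles)
  expect_equal(a$obsolete, b$obsolete)
  expect_equal(a$atoms, b$atoms, tolerance = 1e-8)
  expect_equal(a$bonds, b$bonds)
}

expect_restraints_equal <- function(a, b) {
  expect_equal(a$component_id, b$component_id)
  expect_equal(a$variant, b$variant)
  expect_equal(a$atoms, b$atoms)
  for (f in c("bonds", "angles", "torsions", "planes", "chirals")) {
    expect_equal(as.data.frame(a[[f]]), as.data.frame(b[[f]]),
                 tolerance = 1e-8, label = f)
  }
}

two_atom_toy <- function(dist) {
  chemical_component(
    id = "TOY", name = "one-bond toy",
    atoms = tibble::tibble(atom = c("C1", "O1"), element = c("C", "O"),
                           charge = 0L, x = c(0, dist), y = 0, z = 0),
    bonds = tibble::tibble(atom_1 = "C1", atom_2 = "O1", order = "single"))
}
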