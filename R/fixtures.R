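# Deterministic synthetic components and reference tables so every module
# is testable without downloading dictionary entries. Geometries are
# idealised: standard bond lengths (C-C 1.54/1.52, C=O 1.23, delocalised
# carboxylate C-O 1.25, C-OH 1.31, aromatic C-C 1.39, C-H 1.09, N-H 1.01,
# O-H 0.98 Angstrom), tetrahedral
# 109.47 deg at sp3 centres and 120 deg at sp2 centres.

FIXTURE_NAMES <- c("ethane", "acetate", "benzene", "trp_sidechain",
                   "dipeptide_like", "dicarboxylate")

TETRA <- 109.4712206344907  # acos(-1/3) in degrees

#' Build a synthetic chemical component
#'
#' Catalogue of six idealised components exercising the whole pipeline:
#' `ethane` (a single rotatable bond), `acetate` (charged carboxylate,
#' protonatable), `benzene` (aromatic plane), `trp_sidechain` (a branched
#' alkene toy whose CA-CB-CG-CD1 torsion plays the role of a chi2 angle
#' with discrete conformers), `dipeptide_like` (a polymerisable amino-acid
#' entity carrying the H2/OXT/HXT terminus atoms and a chiral CA) and
#' `dicarboxylate` (two protonatable sites). Output is deterministic:
#' repeated calls give identical components.
#'
#' @param name One of `r toString(FIXTURE_NAMES)`.
#' @return A [chemical_component()] with idealised coordinates, full
#'   hydrogens and formal charges.
#' @examples
#' make_fixture("acetate")
#' @export
make_fixture <- function(name) {
  switch(
    name,
    ethane = fixture_ethane(),
    acetate = fixture_acetate(),
    benzene = fixture_benzene(),
    trp_sidechain = fixture_trp_sidechain(),
    dipeptide_like = fixture_dipeptide_like(),
    dicarboxylate = fixture_dicarboxylate(),
    stop("unknown fixture '", name, "'; available: ", toString(FIXTURE_NAMES))
  )
}

fixture_component <- function(id, name, type, atom_list, bond_list,
                              smiles = "") {
  atoms <- tibble::tibble(
    atom = names(atom_list),
    element = vapply(atom_list, function(a) a$el, character(1), USE.NAMES = FALSE),
    charge = vapply(atom_list, function(a) as.integer(a$q %||% 0L), integer(1),
                    USE.NAMES = FALSE),
    x = vapply(atom_list, function(a) a$xyz[1], numeric(1), USE.NAMES = FALSE),
    y = vapply(atom_list, function(a) a$xyz[2], numeric(1), USE.NAMES = FALSE),
    z = vapply(atom_list, function(a) a$xyz[3], numeric(1), USE.NAMES = FALSE)
  )
  bonds <- tibble::tibble(
    atom_1 = vapply(bond_list, `[[`, character(1), 1),
    atom_2 = vapply(bond_list, `[[`, character(1), 2),
    order = vapply(bond_list, `[[`, character(1), 3)
  )
  chemical_component(id = id, name = name, type = type, atoms = atoms,
                     bonds = bonds, smiles = smiles)
}

at <- function(el, xyz, q = 0L) list(el = el, xyz = xyz, q = q)

fixture_ethane <- function() {
  c1 <- c(0, 0, 0)
  c2 <- c(1.54, 0, 0)
  dummy <- c(1.54, 1, 0)
  h1 <- lapply(c(0, 120, 240), function(t) place_atom(dummy, c2, c1, 1.09, TETRA, t))
  h2 <- lapply(c(60, 180, 300), function(t) place_atom(h1[[1]], c1, c2, 1.09, TETRA, t))
  fixture_component(
    "ETH", "ethane", "non-polymer",
    list(C1 = at("C", c1), C2 = at("C", c2),
         H11 = at("H", h1[[1]]), H12 = at("H", h1[[2]]), H13 = at("H", h1[[3]]),
         H21 = at("H", h2[[1]]), H22 = at("H", h2[[2]]), H23 = at("H", h2[[3]])),
    list(c("C1", "C2", "single"),
         c("C1", "H11", "single"), c("C1", "H12", "single"),
         c("C1", "H13", "single"),
         c("C2", "H21", "single"), c("C2", "H22", "single"),
         c("C2", "H23", "single")),
    smiles = "CC"
  )
}

fixture_acetate <- function() {
  c2 <- c(0, 0, 0)                       # methyl carbon
  c1 <- c(1.52, 0, 0)                    # carboxyl carbon
  # delocalised carboxylate: both C-O distances equal
  o1 <- c1 + 1.25 * c(cos(pi / 3), sin(pi / 3), 0)
  o2 <- c1 + 1.25 * c(cos(pi / 3), -sin(pi / 3), 0)
  h <- lapply(c(0, 120, 240), function(t) place_atom(o1, c1, c2, 1.09, TETRA, t))
  fixture_component(
    "ACT", "acetate", "non-polymer",
    list(C1 = at("C", c1), C2 = at("C", c2),
         O1 = at("O", o1), O2 = at("O", o2, q = -1L),
         H21 = at("H", h[[1]]), H22 = at("H", h[[2]]), H23 = at("H", h[[3]])),
    list(c("C1", "C2", "single"), c("C1", "O1", "double"),
         c("C1", "O2", "single"),
         c("C2", "H21", "single"), c("C2", "H22", "single"),
         c("C2", "H23", "single")),
    smiles = "CC(=O)[O-]"
  )
}

fixture_benzene <- function() {
  rc <- 1.39          # ring radius equals the aromatic bond length
  rh <- rc + 1.09
  atoms <- list()
  bonds <- list()
  for (i in 1:6) {
    th <- (i - 1) * pi / 3
    atoms[[paste0("C", i)]] <- at("C", c(rc * cos(th), rc * sin(th), 0))
    atoms[[paste0("H", i)]] <- at("H", c(rh * cos(th), rh * sin(th), 0))
    bonds[[length(bonds) + 1L]] <- c(paste0("C", i), paste0("C", i %% 6 + 1), "aromatic")
    bonds[[length(bonds) + 1L]] <- c(paste0("C", i), paste0("H", i), "single")
  }
  fixture_component("BNZ", "benzene", "non-polymer", atoms, bonds,
                    smiles = "c1ccccc1")
}

fixture_trp_sidechain <- function() {
  ca <- c(0, 0, 0)
  cb <- c(1.54, 0, 0)
  cg <- place_atom(c(0, 1, 0), ca, cb, 1.50, TETRA, 0)
  cd1 <- place_atom(ca, cb, cg, 1.33, 120, 90)   # the chi2-like torsion = 90
  cd2 <- cg + 1.50 * {
    v <- -((cb - cg) / vnorm(cb - cg) + (cd1 - cg) / vnorm(cd1 - cg))
    v / vnorm(v)
  }
  ha <- lapply(c(60, 180, 300), function(t) place_atom(cg, cb, ca, 1.09, TETRA, t))
  hb <- lapply(c(120, -120), function(t) place_atom(ca, cg, cb, 1.09, TETRA, t))
  hd1 <- lapply(c(0, 180), function(t) place_atom(cb, cg, cd1, 1.08, 120, t))
  hd2 <- lapply(c(60, 180, 300), function(t) place_atom(cd1, cg, cd2, 1.09, TETRA, t))
  fixture_component(
    "TRX", "tryptophan side-chain toy", "non-polymer",
    list(CA = at("C", ca), CB = at("C", cb), CG = at("C", cg),
         CD1 = at("C", cd1), CD2 = at("C", cd2),
         HA1 = at("H", ha[[1]]), HA2 = at("H", ha[[2]]), HA3 = at("H", ha[[3]]),
         HB1 = at("H", hb[[1]]), HB2 = at("H", hb[[2]]),
         HD11 = at("H", hd1[[1]]), HD12 = at("H", hd1[[2]]),
         HD21 = at("H", hd2[[1]]), HD22 = at("H", hd2[[2]]),
         HD23 = at("H", hd2[[3]])),
    list(c("CA", "CB", "single"), c("CB", "CG", "single"),
         c("CG", "CD1", "double"), c("CG", "CD2", "single"),
         c("CA", "HA1", "single"), c("CA", "HA2", "single"),
         c("CA", "HA3", "single"),
         c("CB", "HB1", "single"), c("CB", "HB2", "single"),
         c("CD1", "HD11", "single"), c("CD1", "HD12", "single"),
         c("CD2", "HD21", "single"), c("CD2", "HD22", "single"),
         c("CD2", "HD23", "single")),
    smiles = "CCC(=C)C"
  )
}

fixture_dipeptide_like <- function() {
  n <- c(0, 0, 0)
  ca <- c(1.47, 0, 0)
  c <- place_atom(c(1.47, 1, 0), n, ca, 1.52, TETRA, 0)
  o <- place_atom(n, ca, c, 1.23, 120, 0)
  oxt <- c + 1.31 * {
    v <- -((ca - c) / vnorm(ca - c) + (o - c) / vnorm(o - c))
    v / vnorm(v)
  }
  hxt <- place_atom(o, c, oxt, 0.98, 106, 180)
  cb <- place_atom(c, n, ca, 1.53, TETRA, 120)
  ha <- place_atom(c, n, ca, 1.09, TETRA, -120)
  hn <- lapply(c(60, 300), function(t) place_atom(c, ca, n, 1.01, TETRA, t))
  hb <- lapply(c(0, 120, 240), function(t) place_atom(n, ca, cb, 1.09, TETRA, t))
  fixture_component(
    "DPL", "dipeptide-like entity", "polymerisable-amino-acid",
    list(N = at("N", n), CA = at("C", ca), C = at("C", c),
         O = at("O", o), OXT = at("O", oxt), CB = at("C", cb),
         H = at("H", hn[[1]]), H2 = at("H", hn[[2]]),
         HA = at("H", ha), HXT = at("H", hxt),
         HB1 = at("H", hb[[1]]), HB2 = at("H", hb[[2]]), HB3 = at("H", hb[[3]])),
    list(c("N", "CA", "single"), c("CA", "C", "single"),
         c("C", "O", "double"), c("C", "OXT", "single"),
         c("OXT", "HXT", "single"), c("CA", "CB", "single"),
         c("N", "H", "single"), c("N", "H2", "single"),
         c("CA", "HA", "single"),
         c("CB", "HB1", "single"), c("CB", "HB2", "single"),
         c("CB", "HB3", "single")),
    smiles = "CC(N)C(=O)O"
  )
}

fixture_dicarboxylate <- function() {
  c2 <- c(0, 0, 0)
  c1 <- c(1.52, 0, 0)
  c3 <- place_atom(c(1.52, 1, 0), c1, c2, 1.52, TETRA, 0)
  o1 <- place_atom(c3, c2, c1, 1.25, 120, 0)
  o2 <- place_atom(c3, c2, c1, 1.25, 120, 180)
  o3 <- place_atom(c1, c2, c3, 1.25, 120, 0)
  o4 <- place_atom(c1, c2, c3, 1.25, 120, 180)
  h <- lapply(c(120, -120), function(t) place_atom(c3, c1, c2, 1.09, TETRA, t))
  fixture_component(
    "DCX", "malonate-like dicarboxylate", "non-polymer",
    list(C1 = at("C", c1), C2 = at("C", c2), C3 = at("C", c3),
         O1 = at("O", o1), O2 = at("O", o2, q = -1L),
         O3 = at("O", o3), O4 = at("O", o4, q = -1L),
         H21 = at("H", h[[1]]), H22 = at("H", h[[2]])),
    list(c("C1", "C2", "single"), c("C2", "C3", "single"),
         c("C1", "O1", "double"), c("C1", "O2", "single"),
         c("C3", "O3", "double"), c("C3", "O4", "single"),
         c("C2", "H21", "single"), c("C2", "H22", "single")),
    smiles = "[O-]C(=O)CC(=O)[O-]"
  )
}

#' Build a synthetic reference bond/angle table from components
#'
#' Stands in for a small-molecule distribution lookup: every distinct typed
#' bond/angle key observed across `components` gets one entry with ideal =
#' mean measured value, the supplied standard deviation and n_obs = number
#' of occurrences. Keys listed in `zero_sd_keys` get sd = 0, which lets
#' tests exercise the validation floors.
#'
#' @param components A [chemical_component()] or list of them, with
#'   coordinates.
#' @param sd_bond Standard deviation assigned to bond entries (Angstrom).
#' @param sd_angle Standard deviation assigned to angle entries (degrees).
#' @param zero_sd_keys Optional character vector of `type_key` values whose
#'   sd is forced to 0.
#' @return A `reference_table` tibble with columns `kind`, `type_key`,
#'   `ideal`, `sd`, `n_obs`.
#' @examples
#' make_reference_table(make_fixture("acetate"))
#' @export
make_reference_table <- function(components, sd_bond = 0.01, sd_angle = 1.5,
                                 zero_sd_keys = NULL) {
  if (inherits(components, "chemical_component")) components <- list(components)
  obs <- dplyr::bind_rows(purrr::map(components, measure_typed_metrics))
  tab <- obs |>
    dplyr::group_by(.data$kind, .data$type_key) |>
    dplyr::summarise(ideal = mean(.data$observed), n_obs = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(sd = ifelse(.data$kind == "bond", sd_bond, sd_angle)) |>
    dplyr::select("kind", "type_key", "ideal", "sd", "n_obs")
  if (!is.null(zero_sd_keys)) {
    tab$sd[tab$type_key %in% zero_sd_keys] <- 0
  }
  as_reference_table(tab)
}

# every measured bond length and valence angle of a component, with its
# canonical type key
measure_typed_metrics <- function(comp) {
  ic <- perceive_internal_coordinates(comp)
  coords <- component_coordinates(comp)
  types <- atom_type_codes(comp)
  bonds <- ic$bonds |>
    dplyr::mutate(
      kind = "bond",
      type_key = bond_type_key(types, .data$atom_1, .data$atom_2),
      observed = purrr::map2_dbl(.data$atom_1, .data$atom_2,
                                 ~ bond_length(coords[.x, ], coords[.y, ])),
      atoms = paste(.data$atom_1, .data$atom_2, sep = "-")
    )
  angles <- ic$angles |>
    dplyr::mutate(
      kind = "angle",
      type_key = angle_type_key(types, .data$atom_1, .data$atom_2, .data$atom_3),
      observed = purrr::pmap_dbl(
        list(.data$atom_1, .data$atom_2, .data$atom_3),
        function(a, b, c) bond_angle(coords[a, ], coords[b, ], coords[c, ])),
      atoms = paste(.data$atom_1, .data$atom_2, .data$atom_3, sep = "-")
    )
  dplyr::bind_rows(
    bonds[, c("kind", "type_key", "observed", "atoms")],
    angles[, c("kind", "type_key", "observed", "atoms")]
  )
}

#' Randomly displace the coordinates of a component
#'
#' Adds i.i.d. Gaussian noise (Mersenne-Twister generator with inversion
#' normal sampling, so output is reproducible across platforms for a given
#' seed) to every Cartesian coordinate.
#'
#' @param comp A [chemical_component()] with coordinates.
#' @param sigma Displacement standard deviation per coordinate (Angstrom).
#' @param seed Integer seed.
#' @return A coordinate matrix (atoms x 3) like [component_coordinates()].
#' @export
perturb_coordinates <- function(comp, sigma, seed) {
  stopifnot(sigma >= 0)
  coords <- component_coordinates(comp)
  if (sigma == 0) return(coords)
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  coords + matrix(stats::rnorm(length(coords), sd = sigma), ncol = 3)
}
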