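# ChemicalComponent: one CCD-style entity (atoms, bonds, coordinates, SMILES).

PERIODIC_TABLE <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf"
)

# Elements NOT treated as metals for pipeline eligibility: the organic set,
# metalloids commonly found in ligands, the halogens and the noble gases.
# Everything else in the periodic table counts as a metal.
NONMETAL_ELEMENTS <- c(
  "H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "As", "Se", "Br",
  "Te", "I", "He", "Ne", "Ar", "Kr", "Xe", "Rn"
)

# van der Waals radii (Angstrom, Bondi 1964 with common extensions); used by
# the repulsive-only nonbonded term of the minimiser.
VDW_RADII <- c(
  H = 1.20, He = 1.40, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  Ne = 1.54, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Ar = 1.88,
  As = 1.85, Se = 1.90, Br = 1.85, Kr = 2.02, Te = 2.06, I = 1.98,
  Xe = 2.16, Rn = 2.20
)

COMPONENT_TYPES <- c(
  "non-polymer", "polymerisable-amino-acid", "polymerisable-nucleic-acid",
  "saccharide", "other"
)

BOND_ORDERS <- c("single", "double", "triple", "aromatic")

#' Construct a chemical component
#'
#' A `chemical_component` is the package's representation of one Chemical
#' Component Dictionary style entity: an id (1-5 alphanumeric characters,
#' long ids supporting the extended 5-character ligand codes), an atom table,
#' a bond table, optional Cartesian coordinates, a SMILES string and type
#' flags. Atom names are unique; bonds reference listed atoms only; either
#' every atom has coordinates or none does.
#'
#' @param id Component id, 1-5 alphanumeric characters.
#' @param atoms Data frame with columns `atom` (name), `element` (IUPAC
#'   symbol), `charge` (integer formal charge) and optionally `x`, `y`, `z`
#'   (Angstrom).
#' @param bonds Data frame with columns `atom_1`, `atom_2`, `order`
#'   (one of `r toString(BOND_ORDERS)`).
#' @param name Human-readable component name.
#' @param type Component type, one of `r toString(COMPONENT_TYPES)`.
#' @param smiles SMILES descriptor (may be empty).
#' @param obsolete Logical: entity flagged obsolete in its dictionary.
#' @param parent_id Optional parent component id (non-standard residues).
#' @param variant Protonation-variant label, `"neutral"` or `"protonated"`.
#' @return An object of class `chemical_component`.
#' @examples
#' comp <- make_fixture("acetate")
#' comp
#' @export
chemical_component <- function(id, atoms, bonds, name = id,
                               type = "non-polymer", smiles = "",
                               obsolete = FALSE, parent_id = NULL,
                               variant = "neutral") {
  atoms <- tibble::as_tibble(atoms)
  bonds <- tibble::as_tibble(bonds)
  if (!all(c("atom", "element", "charge") %in% names(atoms))) {
    stop("`atoms` needs columns atom, element, charge")
  }
  if (nrow(bonds) && !all(c("atom_1", "atom_2", "order") %in% names(bonds))) {
    stop("`bonds` needs columns atom_1, atom_2, order")
  }
  if (!nrow(bonds)) {
    bonds <- tibble::tibble(atom_1 = character(0), atom_2 = character(0),
                            order = character(0))
  }
  has_xyz <- all(c("x", "y", "z") %in% names(atoms))
  if (!has_xyz) atoms$x <- atoms$y <- atoms$z <- NA_real_
  atoms <- atoms[, c("atom", "element", "charge", "x", "y", "z")]
  atoms$charge <- as.integer(atoms$charge)
  comp <- structure(
    list(id = id, name = name, type = type, atoms = atoms, bonds = bonds,
         smiles = smiles, obsolete = isTRUE(obsolete),
         parent_id = parent_id, variant = variant),
    class = "chemical_component"
  )
  validate_component(comp)
  comp
}

validate_component <- function(comp) {
  with(comp, {
    if (!grepl("^[A-Za-z0-9]{1,5}$", id)) {
      stop("component id must be 1-5 alphanumeric characters, got '", id, "'")
    }
    if (!type %in% COMPONENT_TYPES) {
      stop("unknown component type '", type, "'")
    }
    if (anyDuplicated(atoms$atom)) {
      stop("duplicate atom names: ",
           toString(unique(atoms$atom[duplicated(atoms$atom)])))
    }
    if (any(!nzchar(atoms$atom))) stop("empty atom name")
    bad_el <- setdiff(unique(atoms$element), PERIODIC_TABLE)
    if (length(bad_el)) stop("unknown element symbol: ", toString(bad_el))
    cc <- is.na(atoms$x) | is.na(atoms$y) | is.na(atoms$z)
    if (any(cc) && !all(cc)) {
      stop("coordinates must be present for all atoms or none")
    }
    if (nrow(bonds)) {
      unk <- setdiff(c(bonds$atom_1, bonds$atom_2), atoms$atom)
      if (length(unk)) {
        stop("bond references unknown atom: ", toString(unk),
             call. = FALSE)
      }
      if (any(bonds$atom_1 == bonds$atom_2)) stop("self-bond")
      key <- paste(pmin(bonds$atom_1, bonds$atom_2),
                   pmax(bonds$atom_1, bonds$atom_2))
      if (anyDuplicated(key)) stop("duplicate bond")
      if (!all(bonds$order %in% BOND_ORDERS)) {
        stop("unknown bond order: ",
             toString(setdiff(bonds$order, BOND_ORDERS)))
      }
    }
  })
  invisible(comp)
}

#' @export
print.chemical_component <- function(x, ...) {
  cat(sprintf("<chemical_component> %s (%s)\n", x$id, x$name))
  cat(sprintf("  type: %s%s%s | %d atoms, %d bonds | net charge %+d\n",
              x$type,
              if (x$obsolete) " [obsolete]" else "",
              if (!identical(x$variant, "neutral")) paste0(" [", x$variant, "]") else "",
              nrow(x$atoms), nrow(x$bonds), sum(x$atoms$charge)))
  if (nzchar(x$smiles)) cat("  smiles:", x$smiles, "\n")
  invisible(x)
}

#' Does the component carry Cartesian coordinates?
#' @param comp A `chemical_component`.
#' @return Logical scalar.
#' @export
has_coordinates <- function(comp) {
  nrow(comp$atoms) > 0 && !anyNA(comp$atoms$x)
}

#' Coordinates of a component as a matrix
#'
#' @param comp A `chemical_component` with coordinates.
#' @return Numeric matrix, one row per atom (row names = atom names),
#'   columns x, y, z in Angstrom.
#' @export
component_coordinates <- function(comp) {
  if (!has_coordinates(comp)) stop("component '", comp$id, "' has no coordinates")
  m <- as.matrix(comp$atoms[, c("x", "y", "z")])
  rownames(m) <- comp$atoms$atom
  m
}

#' Replace the coordinates of a component
#'
#' @param comp A `chemical_component`.
#' @param coords Numeric matrix (atoms x 3) in the component's atom order,
#'   or with row names matching the atom names.
#' @return The component with updated coordinates.
#' @export
set_coordinates <- function(comp, coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(comp$atoms) || ncol(coords) != 3) {
    stop("coordinate matrix must be ", nrow(comp$atoms), " x 3")
  }
  if (!is.null(rownames(coords))) coords <- coords[comp$atoms$atom, , drop = FALSE]
  comp$atoms$x <- coords[, 1]
  comp$atoms$y <- coords[, 2]
  comp$atoms$z <- coords[, 3]
  comp
}

# adjacency list of the bond graph, names -> character vectors of neighbours
bond_adjacency <- function(comp) {
  adj <- stats::setNames(vector("list", nrow(comp$atoms)), comp$atoms$atom)
  adj[] <- list(character(0))
  for (i in seq_len(nrow(comp$bonds))) {
    a <- comp$bonds$atom_1[i]; b <- comp$bonds$atom_2[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# connected-component label per atom (nonbonded term skips cross-fragment
# exclusions)
bond_fragments <- function(comp) {
  adj <- bond_adjacency(comp)
  atoms <- comp$atoms$atom
  frag <- stats::setNames(rep(NA_integer_, length(atoms)), atoms)
  k <- 0L
  for (a in atoms) {
    if (!is.na(frag[[a]])) next
    k <- k + 1L
    queue <- a
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      if (!is.na(frag[[cur]])) next
      frag[[cur]] <- k
      queue <- c(queue, adj[[cur]][is.na(frag[adj[[cur]]])])
    }
  }
  frag
}

# graph distance (number of bonds) between all atom pairs, capped at `cap`
bond_distances <- function(comp, cap = 4L) {
  atoms <- comp$atoms$atom
  n <- length(atoms)
  adj <- bond_adjacency(comp)
  d <- matrix(Inf, n, n, dimnames = list(atoms, atoms))
  diag(d) <- 0
  for (a in atoms) {
    queue <- a
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      if (d[a, cur] >= cap) next
      for (nb in adj[[cur]]) {
        if (d[a, nb] > d[a, cur] + 1) {
          d[a, nb] <- d[a, cur] + 1
          queue <- c(queue, nb)
        }
      }
    }
  }
  d
}

is_hydrogen <- function(comp, atom_names) {
  el <- comp$atoms$element[match(atom_names, comp$atoms$atom)]
  el == "H"
}

# heavy-before-hydrogen, then lexicographic by name (C locale): the
# deterministic priority used whenever a flanking atom must be chosen
atom_priority_order <- function(comp, atom_names) {
  h <- is_hydrogen(comp, atom_names)
  atom_names[order(h, atom_names, method = "radix")]
}
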