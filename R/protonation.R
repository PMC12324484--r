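# Protonation-state variants: refinement against neutron data (and low-pH
# crystal forms) needs restraints for the protonated acid as well as the
# charged species deposited in the dictionary. Deprotonated carboxylates
# C(=O)O(-) are detected from the bond graph and formal charges; each
# charged oxygen receives a hydrogen with standard carboxylic-acid
# geometry: O-H 0.98 Angstrom, C-O-H 106 deg, H anti-periplanar to the
# carbonyl oxygen, in the carboxyl plane.

find_carboxylate_sites <- function(comp) {
  adj <- bond_adjacency(comp)
  el <- stats::setNames(comp$atoms$element, comp$atoms$atom)
  ch <- stats::setNames(comp$atoms$charge, comp$atoms$atom)
  border <- function(a, b) {
    i <- which((comp$bonds$atom_1 == a & comp$bonds$atom_2 == b) |
                 (comp$bonds$atom_1 == b & comp$bonds$atom_2 == a))
    comp$bonds$order[i]
  }
  sites <- list()
  for (c_at in comp$atoms$atom[el[comp$atoms$atom] == "C"]) {
    nb <- adj[[c_at]]
    ox <- nb[el[nb] == "O"]
    if (length(ox) < 2) next
    dbl <- ox[vapply(ox, function(o) border(c_at, o) == "double", logical(1))]
    sng <- ox[vapply(ox, function(o) {
      border(c_at, o) == "single" && ch[[o]] == -1L && length(adj[[o]]) == 1L
    }, logical(1))]
    if (length(dbl) >= 1 && length(sng) >= 1) {
      sites[[length(sites) + 1L]] <- list(carbon = c_at, carbonyl_o = dbl[1],
                                          charged_o = sng[1])
    }
  }
  sites
}

unique_atom_name <- function(existing, base) {
  nm <- base
  i <- 1L
  while (nm %in% existing) {
    nm <- paste0(base, i)
    i <- i + 1L
  }
  nm
}

protonate_sites <- function(comp, sites) {
  out <- comp
  for (s in sites) {
    coords <- component_coordinates(out)
    h_pos <- place_atom(coords[s$carbonyl_o, ], coords[s$carbon, ],
                        coords[s$charged_o, ], 0.98, 106, 180)
    h_name <- unique_atom_name(out$atoms$atom, paste0("H", s$charged_o))
    out$atoms <- dplyr::bind_rows(out$atoms, tibble::tibble(
      atom = h_name, element = "H", charge = 0L,
      x = h_pos[1], y = h_pos[2], z = h_pos[3]))
    out$atoms$charge[out$atoms$atom == s$charged_o] <-
      out$atoms$charge[out$atoms$atom == s$charged_o] + 1L
    out$bonds <- dplyr::bind_rows(out$bonds, tibble::tibble(
      atom_1 = s$charged_o, atom_2 = h_name, order = "single"))
  }
  out$variant <- "protonated"
  validate_component(out)
  out
}

#' Enumerate protonation variants of a component
#'
#' Returns the input (its neutral-variant form) plus protonated variants
#' built by adding a hydrogen to each deprotonated carboxylate oxygen. The
#' default policy emits a single extra variant with every acid site
#' protonated at once (one fully-protonated, low-pH form per component);
#' `policy = "combinatorial"` instead emits one variant per non-empty
#' subset of sites. Components with no protonatable moiety return a list
#' of length one. Added hydrogens are named `H<oxygen-name>`, with digits
#' appended on collision.
#'
#' @param comp A [chemical_component()] with coordinates and formal charges.
#' @param policy `"all"` (default) or `"combinatorial"`.
#' @return A list of [chemical_component()] objects; the first element is
#'   always the input.
#' @examples
#' length(enumerate_protonation_variants(make_fixture("acetate")))  # 2
#' @export
enumerate_protonation_variants <- function(comp, policy = c("all", "combinatorial")) {
  policy <- match.arg(policy)
  sites <- find_carboxylate_sites(comp)
  if (!length(sites)) return(list(comp))
  variants <- list(comp)
  if (policy == "all") {
    variants[[2]] <- protonate_sites(comp, sites)
  } else {
    idx <- seq_along(sites)
    for (k in idx) {
      for (sel in utils::combn(idx, k, simplify = FALSE)) {
        variants[[length(variants) + 1L]] <- protonate_sites(comp, sites[sel])
      }
    }
  }
  variants
}
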