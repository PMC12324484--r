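# Internal-coordinate perception from the bond graph: bond pairs, angle
# triples, representative torsion quads (plus hydrogen-coverage quads so a
# riding-hydrogen model can position every H), planar groups and chiral
# centres with signed volumes.

# sp2 = participates in a double or aromatic bond; sp = triple bond.
atom_hybridisation <- function(comp) {
  hyb <- stats::setNames(rep("sp3", nrow(comp$atoms)), comp$atoms$atom)
  for (i in seq_len(nrow(comp$bonds))) {
    ord <- comp$bonds$order[i]
    ab <- c(comp$bonds$atom_1[i], comp$bonds$atom_2[i])
    if (ord %in% c("double", "aromatic")) {
      hyb[ab][hyb[ab] != "sp"] <- "sp2"
    } else if (ord == "triple") {
      hyb[ab] <- "sp"
    }
  }
  hyb
}

atom_is_aromatic <- function(comp) {
  arom <- stats::setNames(rep(FALSE, nrow(comp$atoms)), comp$atoms$atom)
  sel <- comp$bonds$order == "aromatic"
  arom[unique(c(comp$bonds$atom_1[sel], comp$bonds$atom_2[sel]))] <- TRUE
  arom
}

# element + heavy-graph degree + aromatic flag, e.g. "C3a", "O1": the
# deterministic atom typing used to key reference bond/angle distributions
atom_type_codes <- function(comp) {
  adj <- bond_adjacency(comp)
  deg <- vapply(comp$atoms$atom, function(a) length(adj[[a]]), integer(1))
  arom <- atom_is_aromatic(comp)
  stats::setNames(
    paste0(comp$atoms$element, deg, ifelse(arom[comp$atoms$atom], "a", "")),
    comp$atoms$atom
  )
}

bond_type_key <- function(types, a1, a2) {
  t1 <- types[a1]; t2 <- types[a2]
  paste(pmin(t1, t2), pmax(t1, t2), sep = "-")
}

angle_type_key <- function(types, a1, apex, a3) {
  t1 <- types[a1]; t3 <- types[a3]
  paste0(pmin(t1, t3), "-", pmax(t1, t3), "@", types[apex])
}

best_fit_plane <- function(coords) {
  ctr <- colMeans(coords)
  x <- sweep(coords, 2, ctr)
  ev <- eigen(crossprod(x), symmetric = TRUE)
  normal <- ev$vectors[, 3]
  list(centroid = ctr, normal = normal,
       heights = as.numeric(x %*% normal))
}

# canonical description of the branch rooted at `start`, never crossing
# `blocked`; distinct strings = distinct substituent branches. Uses the
# (depth, element) multiset, which resolves every case arising in practice
# for small ligands.
branch_signature <- function(adj, elements, start, blocked) {
  seen <- c(blocked, start)
  level <- start
  depth <- 0L
  sig <- character(0)
  while (length(level)) {
    sig <- c(sig, paste0(depth, ":", paste(sort(elements[level]), collapse = "")))
    nxt <- unique(unlist(adj[level], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    level <- nxt
    depth <- depth + 1L
  }
  paste(sig, collapse = "|")
}

#' Perceive internal coordinates of a component
#'
#' Derives from the bond graph and Cartesian coordinates: all bond pairs;
#' all valence-angle triples i-j-k (flanks ordered by name); one
#' representative torsion quad per central bond with at least one further
#' neighbour on each side, flanking atoms chosen heavy-before-hydrogen then
#' lexicographically, plus additional quads so that every hydrogen with a
#' 4-atom path through it sits in at least one torsion (required for riding
#' hydrogens); maximal groups of doubly-bonded/aromatic atoms with their
#' direct substituents accepted as planes when the out-of-plane deviation
#' stays within `plane_tolerance`; and chiral centres (atoms with four
#' pairwise-distinct substituent branches) with the signed volume of the
#' first three neighbour vectors.
#'
#' @param comp A [chemical_component()] with coordinates.
#' @param plane_tolerance Maximum out-of-best-fit-plane height (Angstrom)
#'   for a candidate group to be recorded as planar; default 0.02.
#' @return An object of class `internal_coordinates`: a list of tibbles
#'   `bonds`, `angles`, `torsions`, `planes` (long form: plane_id, atom),
#'   `chirals`.
#' @examples
#' ic <- perceive_internal_coordinates(make_fixture("ethane"))
#' ic$torsions
#' @export
perceive_internal_coordinates <- function(comp, plane_tolerance = 0.02) {
  if (!has_coordinates(comp)) {
    stop("component '", comp$id, "' has no coordinates")
  }
  adj <- bond_adjacency(comp)
  coords <- component_coordinates(comp)
  atoms <- comp$atoms$atom
  elements <- stats::setNames(comp$atoms$element, atoms)

  bonds <- tibble::tibble(atom_1 = comp$bonds$atom_1,
                          atom_2 = comp$bonds$atom_2)

  # angles: every bonded path i-j-k, flanks in name order
  ang <- list()
  for (j in atoms) {
    nb <- sort(adj[[j]], method = "radix")
    if (length(nb) < 2) next
    idx <- utils::combn(length(nb), 2)
    ang[[j]] <- tibble::tibble(atom_1 = nb[idx[1, ]], atom_2 = j,
                               atom_3 = nb[idx[2, ]])
  }
  angles <- if (length(ang)) dplyr::bind_rows(ang) else {
    tibble::tibble(atom_1 = character(0), atom_2 = character(0),
                   atom_3 = character(0))
  }

  # torsions: one representative per central bond ...
  tor <- list()
  for (i in seq_len(nrow(comp$bonds))) {
    jk <- sort(c(comp$bonds$atom_1[i], comp$bonds$atom_2[i]), method = "radix")
    j <- jk[1]; k <- jk[2]
    nj <- setdiff(adj[[j]], k)
    nk <- setdiff(adj[[k]], j)
    if (!length(nj) || !length(nk)) next
    tor[[length(tor) + 1L]] <- tibble::tibble(
      atom_1 = atom_priority_order(comp, nj)[1], atom_2 = j,
      atom_3 = k, atom_4 = atom_priority_order(comp, nk)[1]
    )
  }
  torsions <- if (length(tor)) dplyr::bind_rows(tor) else {
    tibble::tibble(atom_1 = character(0), atom_2 = character(0),
                   atom_3 = character(0), atom_4 = character(0))
  }
  # ... plus hydrogen-coverage quads
  hydrogens <- atoms[elements[atoms] == "H"]
  for (h in hydrogens) {
    if (h %in% c(torsions$atom_1, torsions$atom_4)) next
    j <- adj[[h]]
    if (length(j) != 1L) next
    kk <- atom_priority_order(comp, setdiff(adj[[j]], h))
    quad <- NULL
    for (k in kk) {
      ll <- atom_priority_order(comp, setdiff(adj[[k]], c(j, h)))
      if (length(ll)) {
        quad <- c(h, j, k, ll[1])
        break
      }
    }
    if (!is.null(quad)) {
      torsions <- dplyr::bind_rows(torsions, tibble::tibble(
        atom_1 = quad[1], atom_2 = quad[2], atom_3 = quad[3], atom_4 = quad[4]))
    }
  }

  # planar groups: connected clusters of sp2 atoms plus direct substituents
  hyb <- atom_hybridisation(comp)
  sp2 <- atoms[hyb[atoms] == "sp2"]
  assigned <- character(0)
  groups <- list()
  for (seed in sp2) {
    if (seed %in% assigned) next
    cluster <- seed
    queue <- seed
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      nxt <- setdiff(intersect(adj[[cur]], sp2), cluster)
      cluster <- c(cluster, nxt)
      queue <- c(queue, nxt)
    }
    assigned <- c(assigned, cluster)
    grp <- sort(unique(c(cluster, unlist(adj[cluster], use.names = FALSE))),
                method = "radix")
    if (length(grp) < 3) next
    pl <- best_fit_plane(coords[grp, , drop = FALSE])
    if (max(abs(pl$heights)) <= plane_tolerance) {
      groups[[length(groups) + 1L]] <- grp
    }
  }
  planes <- if (length(groups)) {
    dplyr::bind_rows(purrr::imap(groups, function(g, i) {
      tibble::tibble(plane_id = paste0("plan-", i), atom = g)
    }))
  } else {
    tibble::tibble(plane_id = character(0), atom = character(0))
  }

  # chiral centres: four pairwise-distinct substituent branches
  chir <- list()
  for (a in atoms) {
    nb <- adj[[a]]
    if (length(nb) != 4L) next
    sigs <- vapply(nb, function(s) branch_signature(adj, elements, s, a),
                   character(1))
    if (anyDuplicated(sigs)) next
    nbo <- atom_priority_order(comp, nb)[1:3]
    u <- sweep(coords[nbo, , drop = FALSE], 2, coords[a, ])
    vol <- sum(vcross(u[1, ], u[2, ]) * u[3, ])
    chir[[length(chir) + 1L]] <- tibble::tibble(
      centre = a, neighbour_1 = nbo[1], neighbour_2 = nbo[2],
      neighbour_3 = nbo[3], volume = vol)
  }
  chirals <- if (length(chir)) dplyr::bind_rows(chir) else {
    tibble::tibble(centre = character(0), neighbour_1 = character(0),
                   neighbour_2 = character(0), neighbour_3 = character(0),
                   volume = numeric(0))
  }

  structure(
    list(bonds = bonds, angles = angles, torsions = torsions,
         planes = planes, chirals = chirals),
    class = "internal_coordinates"
  )
}

#' @export
print.internal_coordinates <- function(x, ...) {
  cat(sprintf(
    "<internal_coordinates> %d bonds, %d angles, %d torsions, %d planes, %d chiral centres\n",
    nrow(x$bonds), nrow(x$angles), nrow(x$torsions),
    length(unique(x$planes$plane_id)), nrow(x$chirals)))
  invisible(x)
}
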