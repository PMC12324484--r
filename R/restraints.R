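# Restraint generation: ideals measured from a validated geometry, e.s.d.s
# taken as twice the reference s.d. where a typed reference entry matches
# (reference s.d.s being too tight for macromolecular refinement as given),
# class defaults otherwise; torsions periodic (period from central-bond
# hybridisation) or discrete when the caller supplies conformer lists;
# hydrogen restraints complete so a riding-hydrogen model can rebuild every
# H from a bond, an angle and a torsion.

#' Default restraint e.s.d. values
#'
#' Conventional refinement magnitudes used when no reference entry matches
#' a bond or angle, and for the classes the reference tables never cover.
#'
#' @param bond Bond e.s.d., Angstrom.
#' @param angle Angle e.s.d., degrees.
#' @param torsion_periodic E.s.d. for periodic torsions, degrees.
#' @param torsion_discrete E.s.d. for discrete-ideal torsions, degrees.
#' @param plane Per-atom out-of-plane e.s.d., Angstrom.
#' @param chiral Chiral-volume e.s.d., cubic Angstrom.
#' @return A named list of e.s.d. defaults.
#' @export
esd_defaults <- function(bond = 0.02, angle = 3.0, torsion_periodic = 30,
                         torsion_discrete = 15, plane = 0.02, chiral = 0.2) {
  list(bond = bond, angle = angle, torsion_periodic = torsion_periodic,
       torsion_discrete = torsion_discrete, plane = plane, chiral = chiral)
}

new_geometry_restraints <- function(component_id, variant, atoms, bonds,
                                    angles, torsions, planes, chirals) {
  structure(
    list(component_id = component_id, variant = variant, atoms = atoms,
         bonds = bonds, angles = angles, torsions = torsions,
         planes = planes, chirals = chirals),
    class = "geometry_restraints"
  )
}

#' @export
print.geometry_restraints <- function(x, ...) {
  cat(sprintf("<geometry_restraints> %s (%s variant)\n", x$component_id, x$variant))
  cat(sprintf("  %d bonds, %d angles, %d torsions (%d discrete), %d planes, %d chirals over %d atoms\n",
              nrow(x$bonds), nrow(x$angles), nrow(x$torsions),
              sum(x$torsions$mode == "discrete"),
              length(unique(x$planes$plane_id)), nrow(x$chirals),
              length(x$atoms)))
  invisible(x)
}

restraint_counts <- function(r) {
  c(bonds = nrow(r$bonds), angles = nrow(r$angles), torsions = nrow(r$torsions),
    planes = length(unique(r$planes$plane_id)), chirals = nrow(r$chirals))
}

lookup_reference_sd <- function(reference, kind, keys) {
  if (is.null(reference)) return(rep(NA_real_, length(keys)))
  ref <- reference[reference$kind == kind, ]
  ref$sd[match(keys, ref$type_key)]
}

match_conformers <- function(conformers, a1, a2, a3, a4) {
  if (is.null(conformers)) return(NULL)
  keys <- c(paste(a2, a3, sep = "-"), paste(a3, a2, sep = "-"),
            paste(a1, a2, a3, a4, sep = "-"), paste(a4, a3, a2, a1, sep = "-"))
  hit <- intersect(keys, names(conformers))
  if (length(hit)) conformers[[hit[1]]] else NULL
}

#' Generate geometry restraints from a validated geometry
#'
#' Ideal values are measured directly from the input coordinates, so the
#' input geometry is a zero-residual point of its own restraints. Bond and
#' angle e.s.d.s are twice the reference s.d. when the typed reference
#' table has a matching entry (falling back to `defaults` when there is no
#' match or the doubled s.d. would not be positive); torsions get the
#' periodic default unless a caller-supplied conformer list makes them
#' discrete. Torsion periodicity comes from the central-bond hybridisation:
#' sp3-sp3 gives period 3, sp2-sp2 period 2, anything else period 1.
#' Discrete conformer lists are keyed by central bond (`"CB-CG"`, either
#' order) or the full four-atom path (`"CA-CB-CG-CD1"`).
#'
#' @param comp A [chemical_component()] with coordinates.
#' @param reference Optional `reference_table` (see
#'   [make_reference_table()], [read_reference_table()]).
#' @param defaults E.s.d. defaults, see [esd_defaults()].
#' @param conformers Optional named list of numeric vectors of discrete
#'   ideal torsion values (degrees).
#' @param plane_tolerance Passed to [perceive_internal_coordinates()].
#' @return An object of class `geometry_restraints`.
#' @examples
#' r <- generate_restraints(make_fixture("ethane"))
#' r$torsions
#' @export
generate_restraints <- function(comp, reference = NULL,
                                defaults = esd_defaults(),
                                conformers = NULL, plane_tolerance = 0.02) {
  if (!has_coordinates(comp)) {
    stop("component '", comp$id, "' has no coordinates")
  }
  adj <- bond_adjacency(comp)
  h_atoms <- comp$atoms$atom[comp$atoms$element == "H"]
  lonely <- h_atoms[vapply(adj[h_atoms], length, integer(1)) == 0L]
  if (length(lonely)) {
    stop("integrity error: disconnected hydrogen ", toString(lonely))
  }
  ic <- perceive_internal_coordinates(comp, plane_tolerance = plane_tolerance)
  coords <- component_coordinates(comp)
  types <- atom_type_codes(comp)

  bonds <- ic$bonds |>
    dplyr::mutate(
      ideal = purrr::map2_dbl(.data$atom_1, .data$atom_2,
                              ~ bond_length(coords[.x, ], coords[.y, ])),
      ref_sd = lookup_reference_sd(
        reference, "bond", bond_type_key(types, .data$atom_1, .data$atom_2)),
      esd = ifelse(!is.na(.data$ref_sd) & 2 * .data$ref_sd > 0,
                   2 * .data$ref_sd, defaults$bond)
    ) |>
    dplyr::select("atom_1", "atom_2", "ideal", "esd")

  angles <- ic$angles |>
    dplyr::mutate(
      ideal = purrr::pmap_dbl(
        list(.data$atom_1, .data$atom_2, .data$atom_3),
        function(a, b, c) bond_angle(coords[a, ], coords[b, ], coords[c, ])),
      ref_sd = lookup_reference_sd(
        reference, "angle",
        angle_type_key(types, .data$atom_1, .data$atom_2, .data$atom_3)),
      esd = ifelse(!is.na(.data$ref_sd) & 2 * .data$ref_sd > 0,
                   2 * .data$ref_sd, defaults$angle)
    ) |>
    dplyr::select("atom_1", "atom_2", "atom_3", "ideal", "esd")

  hyb <- atom_hybridisation(comp)
  tq <- ic$torsions
  n_t <- nrow(tq)
  torsions <- tibble::tibble(
    id = character(n_t), atom_1 = tq$atom_1, atom_2 = tq$atom_2,
    atom_3 = tq$atom_3, atom_4 = tq$atom_4,
    mode = character(n_t), ideal = NA_real_,
    ideal_list = vector("list", n_t),
    period = NA_integer_, esd = NA_real_
  )
  if (n_t) {
    base <- paste0("tor_", tq$atom_2, "_", tq$atom_3)
    dup <- stats::ave(seq_len(n_t), base, FUN = seq_along)
    torsions$id <- ifelse(dup == 1L, base, paste0(base, "_h", dup - 1L))
    for (i in seq_len(n_t)) {
      conf <- match_conformers(conformers, tq$atom_1[i], tq$atom_2[i],
                               tq$atom_3[i], tq$atom_4[i])
      if (!is.null(conf)) {
        if (anyDuplicated(wrap_angle(conf) %% 360)) {
          stop("discrete conformer list for ", torsions$id[i],
               " has duplicate values mod 360")
        }
        torsions$mode[i] <- "discrete"
        torsions$ideal_list[[i]] <- as.numeric(conf)
        torsions$esd[i] <- defaults$torsion_discrete
      } else {
        torsions$mode[i] <- "periodic"
        torsions$ideal[i] <- dihedral(coords[tq$atom_1[i], ], coords[tq$atom_2[i], ],
                                      coords[tq$atom_3[i], ], coords[tq$atom_4[i], ])
        h2 <- hyb[c(tq$atom_2[i], tq$atom_3[i])]
        torsions$period[i] <- if (all(h2 == "sp3")) 3L
          else if (all(h2 == "sp2")) 2L else 1L
        torsions$esd[i] <- defaults$torsion_periodic
      }
    }
  }

  planes <- ic$planes
  planes$esd <- rep(defaults$plane, nrow(planes))

  chirals <- ic$chirals |>
    dplyr::transmute(
      id = paste0("chir_", dplyr::row_number()),
      centre = .data$centre, neighbour_1 = .data$neighbour_1,
      neighbour_2 = .data$neighbour_2, neighbour_3 = .data$neighbour_3,
      volume_ideal = .data$volume, esd = defaults$chiral,
      both_signs = FALSE
    )

  r <- new_geometry_restraints(
    component_id = comp$id, variant = comp$variant,
    atoms = comp$atoms$atom, bonds = bonds, angles = angles,
    torsions = torsions, planes = planes, chirals = chirals
  )
  check_hydrogen_completeness(comp, r)
  r
}

# every H needs a bond, an angle, and (when a 4-atom path through it
# exists) a torsion restraint, otherwise riding positioning is impossible
check_hydrogen_completeness <- function(comp, r) {
  h <- intersect(comp$atoms$atom[comp$atoms$element == "H"], r$atoms)
  adj <- bond_adjacency(comp)
  in_bond <- h %in% c(r$bonds$atom_1, r$bonds$atom_2)
  in_angle <- h %in% c(r$angles$atom_1, r$angles$atom_3)
  in_tor <- h %in% c(r$torsions$atom_1, r$torsions$atom_4)
  needs_angle <- vapply(h, function(a) {
    any(vapply(adj[[a]], function(p) length(adj[[p]]) >= 2, logical(1)))
  }, logical(1))
  needs_tor <- vapply(h, function(a) {
    any(vapply(adj[[a]], function(p) {
      any(vapply(setdiff(adj[[p]], a), function(k)
        length(setdiff(adj[[k]], c(p, a))) > 0, logical(1)))
    }, logical(1)))
  }, logical(1))
  bad <- h[!in_bond | (needs_angle & !in_angle) | (needs_tor & !in_tor)]
  if (length(bad)) {
    stop("integrity error: incomplete hydrogen restraints for ", toString(bad))
  }
  invisible(TRUE)
}

POLYMER_TERMINUS_ATOMS <- c("H2", "OXT", "HXT")

#' Remove polymerisation-terminus restraints
#'
#' Polymerisable amino-acid entities are stored as free molecules but used
#' linked into chains, where the terminus atoms H2, OXT and HXT do not
#' exist; every restraint referencing any of them is dropped and the atoms
#' leave the restraint block's atom list. All other restraints are
#' preserved verbatim; components of any other type (or without those
#' atoms) pass through unchanged, and the operation is idempotent.
#'
#' @param restraints A `geometry_restraints` object.
#' @param comp The owning [chemical_component()].
#' @return The trimmed `geometry_restraints`.
#' @export
trim_polymer_termini <- function(restraints, comp) {
  if (comp$type != "polymerisable-amino-acid") return(restraints)
  drop <- intersect(POLYMER_TERMINUS_ATOMS, restraints$atoms)
  if (!length(drop)) return(restraints)
  touches <- function(df, cols) {
    if (!nrow(df)) return(rep(FALSE, 0))
    Reduce(`|`, lapply(cols, function(cl) df[[cl]] %in% drop))
  }
  r <- restraints
  r$atoms <- setdiff(r$atoms, drop)
  r$bonds <- r$bonds[!touches(r$bonds, c("atom_1", "atom_2")), ]
  r$angles <- r$angles[!touches(r$angles, c("atom_1", "atom_2", "atom_3")), ]
  r$torsions <- r$torsions[!touches(r$torsions, paste0("atom_", 1:4)), ]
  r$planes <- r$planes[!r$planes$atom %in% drop, ]
  keep_planes <- names(which(table(r$planes$plane_id) >= 3))
  r$planes <- r$planes[r$planes$plane_id %in% keep_planes, ]
  r$chirals <- r$chirals[!touches(
    r$chirals, c("centre", "neighbour_1", "neighbour_2", "neighbour_3")), ]
  r
}
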