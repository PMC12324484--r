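# Monomer-library restraint CIF dialect and the delimited reference-table
# format. Discrete-ideal torsions have no column in the classic dialect, so
# they are serialised as one row per ideal value with ids suffixed _alt1,
# _alt2, ... and period 1; the reader folds such groups back into a single
# discrete restraint.

#' Write geometry restraints as a monomer-library CIF block
#'
#' Emits `data_comp_<ID>` with the atom list and the `_chem_comp_bond`,
#' `_chem_comp_angle`, `_chem_comp_tor`, `_chem_comp_plane_atom` and
#' `_chem_comp_chir` loops. Chiral rows carry the conventional
#' `volume_sign` (positiv/negativ/both) plus numeric `volume_ideal` and
#' `volume_esd` columns so a read reproduces the object exactly.
#'
#' @param restraints A `geometry_restraints` object.
#' @param path Optional output file path (UTF-8).
#' @return The CIF document as a string, invisibly when `path` is given.
#' @seealso [read_restraints_cif()], [generate_restraints()]
#' @export
write_restraints_cif <- function(restraints, path = NULL) {
  r <- restraints
  stopifnot(inherits(r, "geometry_restraints"))
  if (any(c(r$bonds$esd, r$angles$esd, r$torsions$esd, r$planes$esd,
            r$chirals$esd) <= 0)) {
    stop("restraint e.s.d. values must be strictly positive")
  }
  items <- list("_chem_comp.id" = r$component_id,
                "_chem_comp.variant" = r$variant)
  loops <- list(data.frame(
    "_chem_comp_atom.comp_id" = r$component_id,
    "_chem_comp_atom.atom_id" = r$atoms, check.names = FALSE))
  if (nrow(r$bonds)) {
    loops[[length(loops) + 1L]] <- data.frame(
      "_chem_comp_bond.comp_id" = r$component_id,
      "_chem_comp_bond.atom_id_1" = r$bonds$atom_1,
      "_chem_comp_bond.atom_id_2" = r$bonds$atom_2,
      "_chem_comp_bond.value_dist" = cif_num(r$bonds$ideal),
      "_chem_comp_bond.value_dist_esd" = cif_num(r$bonds$esd),
      check.names = FALSE)
  }
  if (nrow(r$angles)) {
    loops[[length(loops) + 1L]] <- data.frame(
      "_chem_comp_angle.comp_id" = r$component_id,
      "_chem_comp_angle.atom_id_1" = r$angles$atom_1,
      "_chem_comp_angle.atom_id_2" = r$angles$atom_2,
      "_chem_comp_angle.atom_id_3" = r$angles$atom_3,
      "_chem_comp_angle.value_angle" = cif_num(r$angles$ideal),
      "_chem_comp_angle.value_angle_esd" = cif_num(r$angles$esd),
      check.names = FALSE)
  }
  if (nrow(r$torsions)) {
    rows <- list()
    for (i in seq_len(nrow(r$torsions))) {
      t <- r$torsions[i, ]
      if (t$mode == "periodic") {
        rows[[length(rows) + 1L]] <- data.frame(
          id = t$id, a1 = t$atom_1, a2 = t$atom_2, a3 = t$atom_3,
          a4 = t$atom_4, value = t$ideal, esd = t$esd, period = t$period)
      } else {
        vals <- t$ideal_list[[1]]
        rows[[length(rows) + 1L]] <- data.frame(
          id = paste0(t$id, "_alt", seq_along(vals)),
          a1 = t$atom_1, a2 = t$atom_2, a3 = t$atom_3, a4 = t$atom_4,
          value = vals, esd = t$esd, period = 1L)
      }
    }
    tor <- do.call(rbind, rows)
    loops[[length(loops) + 1L]] <- data.frame(
      "_chem_comp_tor.comp_id" = r$component_id,
      "_chem_comp_tor.id" = tor$id,
      "_chem_comp_tor.atom_id_1" = tor$a1,
      "_chem_comp_tor.atom_id_2" = tor$a2,
      "_chem_comp_tor.atom_id_3" = tor$a3,
      "_chem_comp_tor.atom_id_4" = tor$a4,
      "_chem_comp_tor.value_angle" = cif_num(tor$value),
      "_chem_comp_tor.value_angle_esd" = cif_num(tor$esd),
      "_chem_comp_tor.period" = as.character(tor$period),
      check.names = FALSE)
  }
  if (nrow(r$planes)) {
    loops[[length(loops) + 1L]] <- data.frame(
      "_chem_comp_plane_atom.comp_id" = r$component_id,
      "_chem_comp_plane_atom.plane_id" = r$planes$plane_id,
      "_chem_comp_plane_atom.atom_id" = r$planes$atom,
      "_chem_comp_plane_atom.dist_esd" = cif_num(r$planes$esd),
      check.names = FALSE)
  }
  if (nrow(r$chirals)) {
    loops[[length(loops) + 1L]] <- data.frame(
      "_chem_comp_chir.comp_id" = r$component_id,
      "_chem_comp_chir.id" = r$chirals$id,
      "_chem_comp_chir.atom_id_centre" = r$chirals$centre,
      "_chem_comp_chir.atom_id_1" = r$chirals$neighbour_1,
      "_chem_comp_chir.atom_id_2" = r$chirals$neighbour_2,
      "_chem_comp_chir.atom_id_3" = r$chirals$neighbour_3,
      "_chem_comp_chir.volume_sign" = ifelse(
        r$chirals$both_signs, "both",
        ifelse(r$chirals$volume_ideal >= 0, "positiv", "negativ")),
      "_chem_comp_chir.volume_ideal" = cif_num(r$chirals$volume_ideal),
      "_chem_comp_chir.volume_esd" = cif_num(r$chirals$esd),
      check.names = FALSE)
  }
  doc <- cif_write_block(paste0("comp_", r$component_id), items, loops)
  if (!is.null(path)) {
    writeLines(doc, path, sep = "", useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}

KNOWN_RESTRAINT_CATEGORIES <- c("_chem_comp_atom", "_chem_comp_bond",
                                "_chem_comp_angle", "_chem_comp_tor",
                                "_chem_comp_plane_atom", "_chem_comp_chir")

#' Read a monomer-library restraint CIF block
#'
#' Inverse of [write_restraints_cif()]; `read(write(x))` reproduces `x`.
#' Torsion rows whose ids share a base name with `_alt<k>` suffixes are
#' folded into one discrete restraint whose ideal list follows the row
#' order. Loops from unknown categories are skipped with a warning.
#'
#' @param text CIF document (string or character vector of lines), one
#'   restraint data block.
#' @return A `geometry_restraints` object.
#' @export
read_restraints_cif <- function(text) {
  blocks <- cif_parse(text)
  if (length(blocks) != 1L) {
    stop("expected exactly one restraint data block, found ", length(blocks))
  }
  blk <- blocks[[1]]
  for (df in blk$loops) {
    cat0 <- sub("\\..*$", "", names(df)[1])
    if (!cat0 %in% KNOWN_RESTRAINT_CATEGORIES) {
      warning("skipping unknown restraint CIF category '", cat0, "'")
    }
  }
  id <- blk$items[["_chem_comp.id"]]
  if (is.null(id)) id <- sub("^comp_", "", blk$name)
  variant <- blk$items[["_chem_comp.variant"]]
  if (is.null(variant) || is.na(variant)) variant <- "neutral"

  atom_df <- find_loop(blk, "_chem_comp_atom.atom_id")
  atoms <- if (is.null(atom_df)) character(0) else atom_df[["_chem_comp_atom.atom_id"]]

  bdf <- find_loop(blk, "_chem_comp_bond.atom_id_1")
  bonds <- if (is.null(bdf)) {
    tibble::tibble(atom_1 = character(0), atom_2 = character(0),
                   ideal = numeric(0), esd = numeric(0))
  } else {
    tibble::tibble(atom_1 = bdf[["_chem_comp_bond.atom_id_1"]],
                   atom_2 = bdf[["_chem_comp_bond.atom_id_2"]],
                   ideal = as.numeric(bdf[["_chem_comp_bond.value_dist"]]),
                   esd = as.numeric(bdf[["_chem_comp_bond.value_dist_esd"]]))
  }

  adf <- find_loop(blk, "_chem_comp_angle.atom_id_1")
  angles <- if (is.null(adf)) {
    tibble::tibble(atom_1 = character(0), atom_2 = character(0),
                   atom_3 = character(0), ideal = numeric(0), esd = numeric(0))
  } else {
    tibble::tibble(atom_1 = adf[["_chem_comp_angle.atom_id_1"]],
                   atom_2 = adf[["_chem_comp_angle.atom_id_2"]],
                   atom_3 = adf[["_chem_comp_angle.atom_id_3"]],
                   ideal = as.numeric(adf[["_chem_comp_angle.value_angle"]]),
                   esd = as.numeric(adf[["_chem_comp_angle.value_angle_esd"]]))
  }

  tdf <- find_loop(blk, "_chem_comp_tor.id")
  torsions <- tibble::tibble(
    id = character(0), atom_1 = character(0), atom_2 = character(0),
    atom_3 = character(0), atom_4 = character(0), mode = character(0),
    ideal = numeric(0), ideal_list = list(), period = integer(0),
    esd = numeric(0))
  if (!is.null(tdf)) {
    ids <- tdf[["_chem_comp_tor.id"]]
    base <- sub("_alt[0-9]+$", "", ids)
    rows <- list()
    for (b in unique(base)) {
      sel <- which(base == b)
      discrete <- length(sel) > 1L || grepl("_alt[0-9]+$", ids[sel[1]])
      first <- sel[1]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = b,
        atom_1 = tdf[["_chem_comp_tor.atom_id_1"]][first],
        atom_2 = tdf[["_chem_comp_tor.atom_id_2"]][first],
        atom_3 = tdf[["_chem_comp_tor.atom_id_3"]][first],
        atom_4 = tdf[["_chem_comp_tor.atom_id_4"]][first],
        mode = if (discrete) "discrete" else "periodic",
        ideal = if (discrete) NA_real_
          else as.numeric(tdf[["_chem_comp_tor.value_angle"]][first]),
        ideal_list = list(if (discrete)
          as.numeric(tdf[["_chem_comp_tor.value_angle"]][sel]) else NULL),
        period = if (discrete) NA_integer_
          else as.integer(tdf[["_chem_comp_tor.period"]][first]),
        esd = as.numeric(tdf[["_chem_comp_tor.value_angle_esd"]][first]))
    }
    torsions <- dplyr::bind_rows(rows)
  }

  pdf <- find_loop(blk, "_chem_comp_plane_atom.plane_id")
  planes <- if (is.null(pdf)) {
    tibble::tibble(plane_id = character(0), atom = character(0), esd = numeric(0))
  } else {
    tibble::tibble(plane_id = pdf[["_chem_comp_plane_atom.plane_id"]],
                   atom = pdf[["_chem_comp_plane_atom.atom_id"]],
                   esd = as.numeric(pdf[["_chem_comp_plane_atom.dist_esd"]]))
  }

  cdf <- find_loop(blk, "_chem_comp_chir.id")
  chirals <- if (is.null(cdf)) {
    tibble::tibble(id = character(0), centre = character(0),
                   neighbour_1 = character(0), neighbour_2 = character(0),
                   neighbour_3 = character(0), volume_ideal = numeric(0),
                   esd = numeric(0), both_signs = logical(0))
  } else {
    tibble::tibble(id = cdf[["_chem_comp_chir.id"]],
                   centre = cdf[["_chem_comp_chir.atom_id_centre"]],
                   neighbour_1 = cdf[["_chem_comp_chir.atom_id_1"]],
                   neighbour_2 = cdf[["_chem_comp_chir.atom_id_2"]],
                   neighbour_3 = cdf[["_chem_comp_chir.atom_id_3"]],
                   volume_ideal = as.numeric(cdf[["_chem_comp_chir.volume_ideal"]]),
                   esd = as.numeric(cdf[["_chem_comp_chir.volume_esd"]]),
                   both_signs = cdf[["_chem_comp_chir.volume_sign"]] == "both")
  }

  new_geometry_restraints(id, variant, atoms, bonds, angles, torsions,
                          planes, chirals)
}

as_reference_table <- function(tab) {
  tab <- tibble::as_tibble(tab)
  need <- c("kind", "type_key", "ideal", "sd", "n_obs")
  if (!all(need %in% names(tab))) {
    stop("reference table needs columns ", toString(need))
  }
  if (!all(tab$kind %in% c("bond", "angle"))) {
    stop("reference kind must be 'bond' or 'angle'")
  }
  if (any(tab$sd < 0) || any(tab$n_obs < 1)) {
    stop("reference table invariants violated: sd >= 0, n_obs >= 1")
  }
  if (anyDuplicated(tab[, c("kind", "type_key")])) {
    stop("duplicate (kind, type_key) in reference table")
  }
  class(tab) <- c("reference_table", class(tibble::tibble()))
  tab
}

#' Read / write a reference bond-angle distribution table
#'
#' Plain CSV with columns `kind` (bond|angle), `type_key`, `ideal`
#' (Angstrom or degrees), `sd` and `n_obs` — the package's stand-in format
#' for small-molecule distribution lookups.
#'
#' @param path File path.
#' @return `read_reference_table()` returns a `reference_table` tibble.
#' @export
read_reference_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           kind = "c", type_key = "c", ideal = "d",
                           sd = "d", n_obs = "i"))
  as_reference_table(tab)
}

#' @rdname read_reference_table
#' @param tab A `reference_table` tibble.
#' @export
write_reference_table <- function(tab, path) {
  readr::write_csv(as_reference_table(tab), path)
  invisible(path)
}
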