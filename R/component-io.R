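# Read/write CCD-style component CIF entries; pipeline eligibility filters.

CCD_TYPE_MAP <- c(
  "NON-POLYMER" = "non-polymer",
  "L-PEPTIDE LINKING" = "polymerisable-amino-acid",
  "D-PEPTIDE LINKING" = "polymerisable-amino-acid",
  "PEPTIDE LINKING" = "polymerisable-amino-acid",
  "RNA LINKING" = "polymerisable-nucleic-acid",
  "DNA LINKING" = "polymerisable-nucleic-acid",
  "SACCHARIDE" = "saccharide",
  "D-SACCHARIDE" = "saccharide",
  "L-SACCHARIDE" = "saccharide",
  "OTHER" = "other"
)

CCD_ORDER_MAP <- c(SING = "single", DOUB = "double", TRIP = "triple",
                   AROM = "aromatic")

find_loop <- function(block, tag) {
  for (df in block$loops) if (tag %in% names(df)) return(df)
  NULL
}

#' Parse a CCD-style component CIF entry
#'
#' Reads one `data_` block in the Chemical Component Dictionary category
#' scheme: `_chem_comp` scalars, a `_chem_comp_atom` loop (atom id, element,
#' formal charge, model Cartesian coordinates) and a `_chem_comp_bond` loop.
#' Unrecognised categories are ignored. A `_pdbx_chem_comp_descriptor` loop
#' of type SMILES populates the SMILES field; `_chem_comp.pdbx_release_status`
#' of `OBS` marks the entity obsolete. Alternate (legacy) atom ids are
#' tolerated in the atom loop but only the primary `atom_id` is used as key.
#'
#' @param text CIF document (single string or character vector of lines)
#'   containing one component data block.
#' @return A [chemical_component()].
#' @seealso [write_component_cif()], [assess_eligibility()]
#' @examples
#' txt <- write_component_cif(make_fixture("ethane"))
#' parse_component_cif(txt)
#' @export
parse_component_cif <- function(text) {
  blocks <- cif_parse(text)
  if (length(blocks) != 1L) {
    stop("expected exactly one component data block, found ", length(blocks))
  }
  blk <- blocks[[1]]
  items <- blk$items
  atom_df <- find_loop(blk, "_chem_comp_atom.atom_id")
  if (is.null(atom_df)) stop("parse error: missing _chem_comp_atom loop")
  need <- c("_chem_comp_atom.atom_id", "_chem_comp_atom.type_symbol")
  if (!all(need %in% names(atom_df))) {
    stop("parse error: _chem_comp_atom loop lacks atom_id/type_symbol")
  }
  el <- atom_df[["_chem_comp_atom.type_symbol"]]
  atoms <- tibble::tibble(
    atom = atom_df[["_chem_comp_atom.atom_id"]],
    element = paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2))),
    charge = {
      ch <- atom_df[["_chem_comp_atom.charge"]]
      if (is.null(ch)) 0L else {
        ch[is.na(ch)] <- "0"
        as.integer(ch)
      }
    }
  )
  xyz_tags <- paste0("_chem_comp_atom.model_Cartn_", c("x", "y", "z"))
  if (all(xyz_tags %in% names(atom_df))) {
    atoms$x <- as.numeric(atom_df[[xyz_tags[1]]])
    atoms$y <- as.numeric(atom_df[[xyz_tags[2]]])
    atoms$z <- as.numeric(atom_df[[xyz_tags[3]]])
  }

  bond_df <- find_loop(blk, "_chem_comp_bond.atom_id_1")
  if (is.null(bond_df)) {
    bonds <- tibble::tibble(atom_1 = character(0), atom_2 = character(0),
                            order = character(0))
  } else {
    ord <- bond_df[["_chem_comp_bond.value_order"]]
    mapped <- unname(CCD_ORDER_MAP[toupper(ord)])
    mapped[is.na(mapped) & tolower(ord) %in% BOND_ORDERS] <-
      tolower(ord)[is.na(mapped) & tolower(ord) %in% BOND_ORDERS]
    if (anyNA(mapped)) {
      stop("parse error in _chem_comp_bond loop: unknown bond order '",
           ord[which(is.na(mapped))[1]], "'")
    }
    bonds <- tibble::tibble(
      atom_1 = bond_df[["_chem_comp_bond.atom_id_1"]],
      atom_2 = bond_df[["_chem_comp_bond.atom_id_2"]],
      order = mapped
    )
    unk <- setdiff(c(bonds$atom_1, bonds$atom_2), atoms$atom)
    if (length(unk)) {
      stop("integrity error: _chem_comp_bond references unknown atom ",
           toString(unk))
    }
  }

  smiles <- ""
  desc <- find_loop(blk, "_pdbx_chem_comp_descriptor.descriptor")
  if (!is.null(desc)) {
    type_col <- desc[["_pdbx_chem_comp_descriptor.type"]]
    hit <- which(toupper(type_col) == "SMILES")
    if (length(hit)) smiles <- desc[["_pdbx_chem_comp_descriptor.descriptor"]][hit[1]]
  }

  ccd_type <- items[["_chem_comp.type"]]
  type <- if (is.null(ccd_type) || is.na(ccd_type)) "non-polymer" else {
    m <- CCD_TYPE_MAP[toupper(ccd_type)]
    if (is.na(m)) "other" else unname(m)
  }
  status <- items[["_chem_comp.pdbx_release_status"]]
  parent <- items[["_chem_comp.mon_nstd_parent_comp_id"]]
  id <- items[["_chem_comp.id"]]
  if (is.null(id)) id <- blk$name

  chemical_component(
    id = id,
    name = if (!is.null(items[["_chem_comp.name"]])) items[["_chem_comp.name"]] else id,
    type = type,
    atoms = atoms,
    bonds = bonds,
    smiles = smiles,
    obsolete = !is.null(status) && !is.na(status) && toupper(status) == "OBS",
    parent_id = if (is.null(parent) || is.na(parent)) NULL else parent
  )
}

#' Write a component as a CCD-style CIF document
#'
#' Emits the `_chem_comp` scalars followed by the atom loop then the bond
#' loop; components without coordinates omit the Cartesian columns. The
#' output re-parses to an equal component.
#'
#' @param comp A [chemical_component()].
#' @param path Optional file path; when given the document is also written
#'   there (UTF-8).
#' @return The CIF document as a single string, invisibly when `path` given.
#' @export
write_component_cif <- function(comp, path = NULL) {
  validate_component(comp)
  items <- list(
    "_chem_comp.id" = comp$id,
    "_chem_comp.name" = comp$name,
    "_chem_comp.type" = names(CCD_TYPE_MAP)[match(comp$type, CCD_TYPE_MAP)],
    "_chem_comp.pdbx_release_status" = if (comp$obsolete) "OBS" else "REL"
  )
  if (!is.null(comp$parent_id)) {
    items[["_chem_comp.mon_nstd_parent_comp_id"]] <- comp$parent_id
  }
  atom_df <- data.frame(
    "_chem_comp_atom.comp_id" = comp$id,
    "_chem_comp_atom.atom_id" = comp$atoms$atom,
    "_chem_comp_atom.type_symbol" = toupper(comp$atoms$element),
    "_chem_comp_atom.charge" = as.character(comp$atoms$charge),
    check.names = FALSE
  )
  if (has_coordinates(comp)) {
    atom_df[["_chem_comp_atom.model_Cartn_x"]] <- cif_num(comp$atoms$x)
    atom_df[["_chem_comp_atom.model_Cartn_y"]] <- cif_num(comp$atoms$y)
    atom_df[["_chem_comp_atom.model_Cartn_z"]] <- cif_num(comp$atoms$z)
  }
  loops <- list(atom_df)
  if (nrow(comp$bonds)) {
    loops[[2]] <- data.frame(
      "_chem_comp_bond.comp_id" = comp$id,
      "_chem_comp_bond.atom_id_1" = comp$bonds$atom_1,
      "_chem_comp_bond.atom_id_2" = comp$bonds$atom_2,
      "_chem_comp_bond.value_order" =
        names(CCD_ORDER_MAP)[match(comp$bonds$order, CCD_ORDER_MAP)],
      check.names = FALSE
    )
  }
  if (nzchar(comp$smiles)) {
    loops[[length(loops) + 1L]] <- data.frame(
      "_pdbx_chem_comp_descriptor.comp_id" = comp$id,
      "_pdbx_chem_comp_descriptor.type" = "SMILES",
      "_pdbx_chem_comp_descriptor.descriptor" = comp$smiles,
      check.names = FALSE
    )
  }
  doc <- cif_write_block(paste0("comp_", comp$id), items, loops)
  if (!is.null(path)) {
    writeLines(doc, path, sep = "", useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}

#' Decide whether a component enters the restraint pipeline
#'
#' Applies the library-construction filters in a fixed order: single-atom
#' entities (mostly metal ions or inert gases), entities containing a metal
#' or metal-cluster atom, standard residues whose restraints are already
#' established, entities flagged obsolete, and the unknown-entity
#' placeholders UNX/UNL. "Metal" means any element outside a fixed allow
#' list of non-metals (`r toString(NONMETAL_ELEMENTS)`); the dictionaries
#' never enumerate the metals, so the allow list is the documented choice.
#'
#' @param comp A [chemical_component()].
#' @param standard_residue_ids Character vector of component ids to treat as
#'   standard residues (amino acids / nucleotides).
#' @return A one-row tibble with columns `id`, `eligible` (logical) and
#'   `reason` (one of ok, single-atom, contains-metal, standard-residue,
#'   obsolete, unknown-entity).
#' @examples
#' assess_eligibility(make_fixture("acetate"))
#' @export
assess_eligibility <- function(comp, standard_residue_ids = character(0)) {
  reason <- if (nrow(comp$atoms) <= 1L) {
    "single-atom"
  } else if (any(!comp$atoms$element %in% NONMETAL_ELEMENTS)) {
    "contains-metal"
  } else if (comp$id %in% standard_residue_ids) {
    "standard-residue"
  } else if (comp$obsolete) {
    "obsolete"
  } else if (toupper(comp$id) %in% c("UNX", "UNL")) {
    "unknown-entity"
  } else {
    "ok"
  }
  tibble::tibble(id = comp$id, eligible = reason == "ok", reason = reason)
}
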