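# Z-score geometry validation: each measured bond and angle with a typed
# reference entry gets z = (observed - ideal) / sd, where sd is floored at
# 0.005 Angstrom (bonds) / 0.75 deg (angles) to rescue reference entries
# with vanishing spread. The geometry is classified from the maximum |z|:
# < 2 "perfect", < 4 "grand", < 6 "ok", else fail; a geometry that needed a
# floor and still passes is reported "ok (reasonable std)" whatever its
# tier, and validations restricted to side-chain atoms carry a
# "(side chain)" modifier.

SD_FLOORS <- c(bond = 0.005, angle = 0.75)

#' Z-score of one geometric metric
#'
#' @param observed,ideal Measured and reference value (same units).
#' @param sd_effective Standard deviation after flooring; must be > 0.
#' @return `(observed - ideal) / sd_effective`.
#' @export
zscore <- function(observed, ideal, sd_effective) {
  if (any(sd_effective <= 0)) {
    stop("sd_effective must be positive; apply the s.d. floors first")
  }
  (observed - ideal) / sd_effective
}

#' Apply the minimum s.d. floor for a metric kind
#'
#' Reference entries backed by very few observations can carry s.d. values
#' of (near) zero, which would fail any geometry; conservative minimum
#' s.d.s of 0.005 Angstrom for bonds and 0.75 deg for angles are
#' substituted instead.
#'
#' @param sd_raw Raw reference s.d. (>= 0), vectorised.
#' @param kind `"bond"` or `"angle"`, vectorised.
#' @return A tibble with columns `sd_effective` and `floored`.
#' @export
apply_sd_floor <- function(sd_raw, kind) {
  stopifnot(all(sd_raw >= 0), all(kind %in% names(SD_FLOORS)))
  fl <- unname(SD_FLOORS[kind])
  tibble::tibble(sd_effective = pmax(sd_raw, fl), floored = sd_raw < fl)
}

#' Classify a geometry from its maximum |Z|
#'
#' Strict thresholds: max |Z| < 2 is "perfect", < 4 "grand", < 6 "ok",
#' otherwise "fail". When any metric needed an s.d. floor and the geometry
#' still passes (< 6), the classification reported is "ok" with
#' `reasonable_std = TRUE` — the designation string becomes
#' "ok (reasonable std)" no matter which tier the Z-score alone would earn.
#'
#' @param max_abs_z Maximum absolute Z-score (>= 0).
#' @param floored_any Did any contributing metric use a floored s.d.?
#' @param side_chain_only Was the metric set restricted to side-chain atoms?
#' @return A one-row tibble: `classification`, `reasonable_std`,
#'   `side_chain`, `designation`.
#' @examples
#' classify(1.9)    # perfect
#' classify(6.0)    # fail (strict thresholds)
#' classify(1.0, floored_any = TRUE)  # ok (reasonable std)
#' @export
classify <- function(max_abs_z, floored_any = FALSE, side_chain_only = FALSE) {
  stopifnot(max_abs_z >= 0)
  tier <- if (max_abs_z < 2) "perfect"
    else if (max_abs_z < 4) "grand"
    else if (max_abs_z < 6) "ok"
    else "fail"
  reasonable <- isTRUE(floored_any) && tier != "fail"
  cls <- if (reasonable) "ok" else tier
  desig <- if (reasonable) "ok (reasonable std)" else cls
  if (isTRUE(side_chain_only)) desig <- paste(desig, "(side chain)")
  tibble::tibble(classification = cls, reasonable_std = reasonable,
                 side_chain = isTRUE(side_chain_only), designation = desig)
}

# default backbone set excluded when restricting to the side chain
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT", "H", "H2", "HA", "HXT")

#' Side-chain atom names of a component
#'
#' All atoms except the peptide-backbone set
#' (`r toString(BACKBONE_ATOMS)`); the partition used when validating only
#' the side chain of a polymerisable entity.
#'
#' @param comp A [chemical_component()].
#' @return Character vector of atom names.
#' @export
side_chain_atoms <- function(comp) {
  setdiff(comp$atoms$atom, BACKBONE_ATOMS)
}

#' Validate a geometry against a reference table
#'
#' Measures every bond length and valence angle of the component, keys it
#' by its canonical atom-typed tuple, and scores each metric with a
#' reference entry; metrics without reference coverage are skipped but
#' counted in the coverage fraction. `restrict_to` limits the metrics to
#' those whose atoms all lie in the given set (e.g.
#' [side_chain_atoms()]) and marks the report side-chain specific.
#'
#' @param comp A [chemical_component()] with coordinates.
#' @param reference A `reference_table`.
#' @param restrict_to Optional character vector of atom names.
#' @return An object of class `validation_report`: a list with `records`
#'   (per-metric tibble with observed, ideal, sd_raw, sd_effective,
#'   floored, z), `max_abs_z`, `rms_z`, `classification`,
#'   `reasonable_std`, `side_chain`, `designation`, `coverage`
#'   (fraction of metrics with a reference entry) and `no_coverage`.
#' @examples
#' act <- make_fixture("acetate")
#' validate_geometry(act, make_reference_table(act))
#' @export
validate_geometry <- function(comp, reference, restrict_to = NULL) {
  reference <- as_reference_table(reference)
  if (!nrow(reference)) stop("empty reference table")
  obs <- measure_typed_metrics(comp)
  side_chain_only <- !is.null(restrict_to)
  if (side_chain_only) {
    keep <- vapply(strsplit(obs$atoms, "-", fixed = TRUE),
                   function(a) all(a %in% restrict_to), logical(1))
    obs <- obs[keep, ]
  }
  n_metrics <- nrow(obs)
  records <- obs |>
    dplyr::left_join(reference, by = c("kind", "type_key"))
  matched <- records[!is.na(records$ideal), ]
  coverage <- if (n_metrics) nrow(matched) / n_metrics else 0
  if (nrow(matched) == 0) {
    cl <- classify(Inf, FALSE, side_chain_only)
    return(structure(
      list(records = tibble::tibble(), max_abs_z = NA_real_, rms_z = NA_real_,
           classification = "fail", reasonable_std = FALSE,
           side_chain = side_chain_only,
           designation = cl$designation, coverage = coverage,
           no_coverage = TRUE),
      class = "validation_report"))
  }
  fl <- apply_sd_floor(matched$sd, matched$kind)
  records <- matched |>
    dplyr::transmute(
      kind = .data$kind, atoms = .data$atoms, type_key = .data$type_key,
      observed = .data$observed, ideal = .data$ideal, sd_raw = .data$sd,
      sd_effective = fl$sd_effective, floored = fl$floored,
      z = zscore(.data$observed, .data$ideal, fl$sd_effective))
  max_abs_z <- max(abs(records$z))
  rms_z <- sqrt(mean(records$z^2))
  cl <- classify(max_abs_z, any(records$floored), side_chain_only)
  structure(
    list(records = records, max_abs_z = max_abs_z, rms_z = rms_z,
         classification = cl$classification,
         reasonable_std = cl$reasonable_std, side_chain = cl$side_chain,
         designation = cl$designation, coverage = coverage,
         no_coverage = FALSE),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", x$designation, "\n")
  if (!x$no_coverage) {
    cat(sprintf("  %d metrics scored (coverage %.0f%%): max |Z| = %.3f, r.m.s.Z = %.3f\n",
                nrow(x$records), 100 * x$coverage, x$max_abs_z, x$rms_z))
  } else {
    cat(sprintf("  no metric had reference coverage (coverage %.0f%%)\n",
                100 * x$coverage))
  }
  invisible(x)
}
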