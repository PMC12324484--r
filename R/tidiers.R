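# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a validation report
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return The per-metric records tibble (kind, atoms, type_key, observed,
#'   ideal, sd_raw, sd_effective, floored, z).
#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) {
  x$records
}

#' One-row summary of a validation report
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return Tibble with `n_metrics`, `coverage`, `max_abs_z`, `rms_z`,
#'   `classification`, `reasonable_std`, `side_chain`, `designation`.
#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(
    n_metrics = nrow(x$records), coverage = x$coverage,
    max_abs_z = x$max_abs_z, rms_z = x$rms_z,
    classification = x$classification, reasonable_std = x$reasonable_std,
    side_chain = x$side_chain, designation = x$designation)
}

#' Tidy a restraint set into one long table
#'
#' @param x A `geometry_restraints`.
#' @param ... Unused.
#' @return Tibble with columns `class` (bond/angle/torsion/plane/chiral),
#'   `id`, `atoms` (hyphen-joined names), `ideal`, `esd`, `mode`, `period`.
#' @method tidy geometry_restraints
#' @export
tidy.geometry_restraints <- function(x, ...) {
  parts <- list(
    tibble::tibble(class = "bond", id = NA_character_,
                   atoms = paste(x$bonds$atom_1, x$bonds$atom_2, sep = "-"),
                   ideal = x$bonds$ideal, esd = x$bonds$esd,
                   mode = NA_character_, period = NA_integer_),
    tibble::tibble(class = "angle", id = NA_character_,
                   atoms = paste(x$angles$atom_1, x$angles$atom_2,
                                 x$angles$atom_3, sep = "-"),
                   ideal = x$angles$ideal, esd = x$angles$esd,
                   mode = NA_character_, period = NA_integer_),
    tibble::tibble(class = "torsion", id = x$torsions$id,
                   atoms = paste(x$torsions$atom_1, x$torsions$atom_2,
                                 x$torsions$atom_3, x$torsions$atom_4,
                                 sep = "-"),
                   ideal = ifelse(x$torsions$mode == "periodic",
                                  x$torsions$ideal, NA_real_),
                   esd = x$torsions$esd, mode = x$torsions$mode,
                   period = x$torsions$period),
    tibble::tibble(class = "plane", id = x$planes$plane_id,
                   atoms = x$planes$atom, ideal = 0,
                   esd = x$planes$esd, mode = NA_character_,
                   period = NA_integer_),
    tibble::tibble(class = "chiral", id = x$chirals$id,
                   atoms = paste(x$chirals$centre, x$chirals$neighbour_1,
                                 x$chirals$neighbour_2, x$chirals$neighbour_3,
                                 sep = "-"),
                   ideal = x$chirals$volume_ideal, esd = x$chirals$esd,
                   mode = NA_character_, period = NA_integer_))
  dplyr::bind_rows(parts)
}

#' One-row summary of a restraint set
#'
#' @param x A `geometry_restraints`.
#' @param ... Unused.
#' @return Tibble of per-class restraint counts plus `component_id` and
#'   `variant`.
#' @method glance geometry_restraints
#' @export
glance.geometry_restraints <- function(x, ...) {
  ct <- restraint_counts(x)
  tibble::tibble(component_id = x$component_id, variant = x$variant,
                 n_atoms = length(x$atoms), n_bonds = ct[["bonds"]],
                 n_angles = ct[["angles"]], n_torsions = ct[["torsions"]],
                 n_planes = ct[["planes"]], n_chirals = ct[["chirals"]])
}

#' One-row summary of a minimisation result
#'
#' @param x A `minimization_result`.
#' @param ... Unused.
#' @return Tibble with `iterations`, `final_residual`, `rmsd_to_start`,
#'   `converged`.
#' @method glance minimization_result
#' @export
glance.minimization_result <- function(x, ...) {
  tibble::tibble(iterations = x$iterations, final_residual = x$final_residual,
                 rmsd_to_start = x$rmsd_to_start, converged = x$converged)
}

#' Z-score profile plot of a validation report
#'
#' One point per scored metric, coloured by kind, with the classification
#' thresholds at |Z| = 2, 4, 6 drawn as reference lines.
#'
#' @param object A `validation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot validation_report
#' @export
autoplot.validation_report <- function(object, ...) {
  if (object$no_coverage) stop("nothing to plot: no metric had reference coverage")
  df <- object$records
  df$atoms <- factor(df$atoms, levels = df$atoms[order(df$kind, df$atoms)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$atoms, y = .data$z,
                                   colour = .data$kind)) +
    ggplot2::geom_hline(yintercept = c(-6, -4, -2, 2, 4, 6),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "Z-score", x = NULL,
                  title = paste("Geometry validation:", object$designation)) +
    ggplot2::theme_minimal()
}

#' Restraint e.s.d. distribution plot
#'
#' @param object A `geometry_restraints`.
#' @param ... Unused.
#' @return A ggplot object: e.s.d. per restraint, faceted by class.
#' @method autoplot geometry_restraints
#' @export
autoplot.geometry_restraints <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$esd)) +
    ggplot2::geom_histogram(bins = 20) +
    ggplot2::facet_wrap(~class, scales = "free") +
    ggplot2::labs(x = "e.s.d. (native units)", y = "restraints",
                  title = paste("Restraints for", object$component_id)) +
    ggplot2::theme_minimal()
}
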