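bin_labels <- c("0", "(0,5)", "[5,10)", "[10,20)", "[20,100]")

#' Bin species by their rounded T percentage
#'
#' Bins follow the published histogram convention and operate on the
#' *rounded* one-decimal percentage, not raw T: a species whose small
#' positive tourism-protected count rounds to 0.0% sits in the zero bin.
#' The bins are exactly 0, (0, 5), \[5, 10), \[10, 20), \[20, 100\], with
#' boundary values 5, 10 and 20 falling into the right-hand bin.
#'
#' @param results Accounting results from [account_species()] or
#'   [fixture_results()]. Species with `coverage == "none"` are excluded.
#' @return A tibble of class `tourism_bins` with columns `bin` (ordered
#'   factor) and `n`.
#' @export
#' @examples
#' bin_T(fixture_results())
bin_T <- function(results) {
  tp <- results$T_percent[results$coverage != "none"]
  assigned <- dplyr::case_when(
    tp == 0 ~ bin_labels[1],
    tp < 5 ~ bin_labels[2],
    tp < 10 ~ bin_labels[3],
    tp < 20 ~ bin_labels[4],
    TRUE ~ bin_labels[5]
  )
  counts <- table(factor(assigned, levels = bin_labels))
  out <- tibble::tibble(
    bin = factor(bin_labels, levels = bin_labels, ordered = TRUE),
    n = as.integer(counts)
  )
  class(out) <- c("tourism_bins", class(out))
  out
}

#' Threatened-species counts per protected area
#'
#' For every protected area with at least one recorded species, counts the
#' distinct species recorded there (`n_species`) and how many of those are
#' recorded in no other protected area (`n_sole`). This is computed on raw
#' occurrence records, before eligibility filtering, matching how reserves
#' supporting the last remaining populations are reported.
#'
#' @param subpopulations Subpopulation records.
#' @return A tibble with `pa_id`, `n_species`, `n_sole`, sorted by
#'   `n_species` descending (ties by `pa_id`).
#' @export
species_per_pa <- function(subpopulations) {
  occ <- subpopulations |>
    tibble::as_tibble() |>
    dplyr::distinct(.data$species_id, .data$pa_id)
  sole <- occ |>
    dplyr::add_count(.data$species_id, name = "n_pas") |>
    dplyr::filter(.data$n_pas == 1)
  occ |>
    dplyr::count(.data$pa_id, name = "n_species") |>
    dplyr::left_join(dplyr::count(sole, .data$pa_id, name = "n_sole"),
                     by = "pa_id") |>
    dplyr::mutate(n_sole = dplyr::coalesce(.data$n_sole, 0L)) |>
    dplyr::arrange(dplyr::desc(.data$n_species), .data$pa_id)
}

#' Coverage funnel from candidate species to computable T
#'
#' Reports, per threat status, the stepwise reduction from all candidate
#' species to those with a computable T: species with no protected-area
#' records at all, species recorded in exactly one protected area, species
#' in two or more, species for which T was computed (`coverage != "none"`),
#' and species whose T covers only part of their known subpopulations.
#' `n_unprotected + n_single_pa + n_multi_pa = n_total` within each status.
#'
#' @param species Species table.
#' @param subpopulations Subpopulation records (raw occurrences).
#' @param results Accounting results for the same species.
#' @return A tibble with one row per threat status.
#' @export
coverage_funnel <- function(species, subpopulations, results) {
  occ <- subpopulations |>
    tibble::as_tibble() |>
    dplyr::distinct(.data$species_id, .data$pa_id) |>
    dplyr::count(.data$species_id, name = "n_pas")
  species |>
    tibble::as_tibble() |>
    dplyr::left_join(occ, by = "species_id") |>
    dplyr::mutate(n_pas = dplyr::coalesce(.data$n_pas, 0L)) |>
    dplyr::left_join(
      dplyr::select(results, "species_id", "coverage"),
      by = "species_id"
    ) |>
    dplyr::mutate(coverage = dplyr::coalesce(.data$coverage, "none")) |>
    dplyr::group_by(threat_status = .data$threat_status) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_unprotected = sum(.data$n_pas == 0),
      n_single_pa = sum(.data$n_pas == 1),
      n_multi_pa = sum(.data$n_pas >= 2),
      n_with_T = sum(.data$coverage != "none"),
      n_partial = sum(.data$coverage == "partial"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$threat_status)
}

#' Histogram of the T bins
#'
#' @param object A `tourism_bins` tibble from [bin_T()].
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.tourism_bins <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin, y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(
      x = "T, percentage of global population protected through tourism",
      y = "Number of species"
    ) +
    ggplot2::theme_minimal()
}

#' Scatter of T against global population on natural-log scales
#'
#' Species with T = 0 are plotted at the smallest positive T in the data
#' (marked by shape) so they remain visible on the log scale.
#'
#' @param results Accounting results with `coverage != "none"` rows.
#' @return A ggplot.
#' @export
plot_T_vs_G <- function(results) {
  d <- dplyr::filter(results, .data$coverage != "none")
  floor_T <- min(d$T[d$T > 0])
  d <- dplyr::mutate(d,
    T_plot = pmax(.data$T, floor_T),
    zero = .data$T == 0
  )
  ggplot2::ggplot(d, ggplot2::aes(x = log(.data$global_population),
                                  y = log(.data$T_plot),
                                  shape = .data$zero,
                                  colour = .data$threat_status)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "ln G", y = "ln T", colour = "IUCN status",
                  shape = "T = 0") +
    ggplot2::theme_minimal()
}
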