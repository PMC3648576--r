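#' Round half away from zero
#'
#' Decimal rounding with halves always moving away from zero (so 4.35 at one
#' decimal becomes 4.4, and -4.35 becomes -4.4), the convention under which
#' the published per-species percentages reproduce. A tiny relative epsilon
#' absorbs binary floating-point representation error, so a value that is
#' exactly a decimal halfway case (e.g. `100 * 87/2000 = 4.35`, stored as
#' 4.3499...96) still rounds upward.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits (default 1).
#' @return `x` rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_up(4.35)   # 4.4, where round() gives 4.3
#' round_half_up(0.75)   # 0.8
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  y <- x * p
  eps <- 1e-9 * pmax(1, abs(y))
  sign(y) * floor(abs(y) + 0.5 + eps) / p
}

#' Render a proportion as a one-decimal percentage
#'
#' The reporting convention for T: `100 * T` rounded to one decimal, half
#' away from zero. Values must be valid proportions.
#'
#' @param T Numeric vector of proportions in \[0, 1\].
#' @return `100 * T` rounded to one decimal.
#' @export
#' @examples
#' render_T_percent(114 / 178)     # 64.0
#' render_T_percent(77 / 1220000)  # 0.0
render_T_percent <- function(T) {
  bad <- !is.na(T) & (T < 0 | T > 1)
  if (any(bad)) {
    abort_validation(sprintf(
      "T must lie in [0, 1]; found %s",
      paste(format(T[bad][seq_len(min(3, sum(bad)))]), collapse = ", ")
    ))
  }
  round_half_up(100 * T, 1)
}

#' Keep the subpopulations that enter the accounting
#'
#' A species' T is computed over resident subpopulations only; for migratory
#' species, over subpopulations at significant breeding sites only. Records
#' with other occupancy classes are dropped; input order is preserved.
#'
#' @param subpopulations Subpopulation records (columns `species_id`, `pa_id`,
#'   `size`, `occupancy`).
#' @param species Species table carrying `species_id` and `migratory`.
#' @return The eligible subset of `subpopulations`, as a tibble.
#' @export
filter_eligible <- function(subpopulations, species) {
  subpopulations |>
    tibble::as_tibble() |>
    dplyr::inner_join(
      dplyr::select(species, "species_id", "migratory"),
      by = "species_id"
    ) |>
    dplyr::filter(
      (.data$migratory & .data$occupancy == "breeding") |
        (!.data$migratory & .data$occupancy == "resident")
    ) |>
    dplyr::select(-"migratory")
}

#' Resolve the tourism revenue share for each protected area
#'
#' Site-level overrides (e.g. private reserves wholly funded by tourism)
#' take precedence; otherwise the national-scale share applies, since parks
#' agencies routinely transfer funds between individual areas. A protected
#' area in a country with no revenue data resolves to `NA` — missing revenue
#' is a value, never an error.
#'
#' @param protected_areas Protected-area table.
#' @param country_revenue Country revenue table.
#' @return A tibble with `pa_id` and the resolved `revenue_share`
#'   (`NA` when unresolvable).
#' @export
resolve_revenue_share <- function(protected_areas, country_revenue) {
  protected_areas |>
    tibble::as_tibble() |>
    dplyr::left_join(
      dplyr::select(country_revenue, "country_code",
                    national_share = "revenue_share"),
      by = "country_code"
    ) |>
    dplyr::transmute(
      pa_id = .data$pa_id,
      revenue_share = dplyr::coalesce(.data$revenue_share_override,
                                      .data$national_share)
    )
}

#' Per-species tourism-protection accounting
#'
#' Computes, for every species, the proportion of its global population whose
#' protection is funded by tourism revenue to protected areas:
#' \deqn{T = \frac{\sum_n S_n R_n}{G}}
#' where the sum runs over the species' eligible subpopulations (see
#' [filter_eligible()]) whose revenue share resolves (see
#' [resolve_revenue_share()]). Areas with zero tourism revenue are included
#' with R = 0; areas whose revenue share is unknown are excluded from the sum
#' and downgrade the species to `coverage = "partial"`. Species with no
#' usable subpopulation get `coverage = "none"` and T = 0, and are excluded
#' from downstream summaries.
#'
#' @param species Species table, or a `tourism_world` from [read_world()] /
#'   [generate_world()] (in which case the remaining arguments are taken from
#'   it).
#' @param subpopulations,protected_areas,country_revenue The other three
#'   tables of the data model.
#' @return A tibble with one row per input species: identification columns,
#'   `n_subpops_used`, `protected_total` (sum of S over used subpopulations),
#'   `tourism_protected` (full-precision sum of S*R), `T`, `T_percent`
#'   (one-decimal), and `coverage` (`"complete"`, `"partial"`, `"none"`).
#' @export
#' @examples
#' w <- generate_world(generator_config(seed = 1, n_species = 30))
#' res <- account_species(w)
#' dplyr::count(res, coverage)
account_species <- function(species, subpopulations = NULL,
                            protected_areas = NULL, country_revenue = NULL) {
  if (inherits(species, "tourism_world")) {
    world <- species
    species <- world$species
    subpopulations <- world$subpopulations
    protected_areas <- world$protected_areas
    country_revenue <- world$country_revenue
  }
  if (any(is.na(species$global_population) | species$global_population < 1)) {
    abort_validation("species table: global_population must be >= 1")
  }

  eligible <- filter_eligible(subpopulations, species) |>
    dplyr::left_join(resolve_revenue_share(protected_areas, country_revenue),
                     by = "pa_id")

  per_species <- eligible |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(
      n_eligible = dplyr::n(),
      n_subpops_used = sum(!is.na(.data$revenue_share)),
      protected_total = sum(.data$size[!is.na(.data$revenue_share)]),
      tourism_protected = sum(.data$size * .data$revenue_share, na.rm = TRUE),
      .groups = "drop"
    )

  res <- species |>
    tibble::as_tibble() |>
    dplyr::left_join(per_species, by = "species_id") |>
    dplyr::mutate(
      n_eligible = dplyr::coalesce(.data$n_eligible, 0L),
      n_subpops_used = dplyr::coalesce(.data$n_subpops_used, 0L),
      protected_total = dplyr::coalesce(.data$protected_total, 0),
      tourism_protected = dplyr::coalesce(.data$tourism_protected, 0)
    )

  over <- res$protected_total > res$global_population
  if (any(over)) {
    abort_data(sprintf(
      "protected subpopulations exceed the global population for: %s",
      paste(res$species_id[over][seq_len(min(5, sum(over)))], collapse = ", ")
    ))
  }

  res |>
    dplyr::mutate(
      T = .data$tourism_protected / .data$global_population,
      T_percent = render_T_percent(.data$T),
      coverage = dplyr::case_when(
        .data$n_subpops_used == 0 ~ "none",
        .data$n_subpops_used < .data$n_eligible ~ "partial",
        TRUE ~ "complete"
      )
    ) |>
    dplyr::select(
      "species_id", "scientific_name", "common_name", "threat_status",
      "global_population", "migratory", "n_subpops_used", "protected_total",
      "tourism_protected", "T", "T_percent", "coverage"
    )
}
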