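# Species whose published T reflects only part of their known subpopulations
# (national revenue data were missing for some of their protected areas).
partial_coverage_species <- c(
  "Copsychus sechellarum", "Zosterops modestus",
  "Phoebastria nigripes", "Phoebetria fusca"
)

#' Bundled reference tables for threatened birds
#'
#' Returns the two published reference tables shipped with the package:
#'
#' * `table1` — the 14 protected areas recording four or more critically
#'   endangered (CR) or endangered (EN) bird species: reserve name, country,
#'   number of CR/EN species recorded, and the number recorded in no other
#'   protected area.
#' * `table2` — the 91 CR/EN bird species with joint subpopulation and
#'   revenue data: scientific and common name, IUCN status, global population
#'   G, the number of protected subpopulations with known S and R, the number
#'   of individuals protected through tourism (SR), and T as a one-decimal
#'   percentage of G.
#'
#' The aggregate `sr` column is the printed quantity; per-subpopulation sizes
#' and revenue shares behind it were not published, so `n_subpops` is carried
#' as data but never used to recompute T.
#'
#' @return A list with tibbles `table1` and `table2`.
#' @export
#' @examples
#' fx <- load_fixtures()
#' nrow(fx$table2)  # 91
load_fixtures <- function() {
  t1_path <- system.file("extdata", "table1_protected_areas.csv",
                         package = "tourishare", mustWork = TRUE)
  t2_path <- system.file("extdata", "table2_species.csv",
                         package = "tourishare", mustWork = TRUE)
  table1 <- readr::read_csv(t1_path, col_types = readr::cols(
    reserve_name = readr::col_character(),
    country = readr::col_character(),
    n_species = readr::col_double(),
    n_sole = readr::col_double()
  ), show_col_types = FALSE)
  table2 <- readr::read_csv(t2_path, col_types = readr::cols(
    scientific_name = readr::col_character(),
    common_name = readr::col_character(),
    threat_status = readr::col_character(),
    global_population = readr::col_double(),
    n_subpops = readr::col_double(),
    sr = readr::col_double(),
    t_percent = readr::col_double()
  ), show_col_types = FALSE)

  if (nrow(table2) != 91 || nrow(table1) != 14) {
    abort_integrity("bundled reference tables are corrupt: expected 91 + 14 rows")
  }
  recomputed <- render_T_percent(table2$sr / table2$global_population)
  if (!identical(recomputed, table2$t_percent)) {
    abort_integrity("bundled reference table2 is internally inconsistent: 100*SR/G does not reproduce the T column")
  }
  list(table1 = table1, table2 = table2)
}

#' Accounting results reconstructed from the bundled species table
#'
#' Converts the published per-species table into the same shape that
#' [account_species()] produces, so the downstream summaries and statistics
#' run unchanged on it. T is recomputed at full precision as `sr /
#' global_population`; per-subpopulation sizes are unpublished, so
#' `protected_total` is `NA`. The four species whose published values covered
#' only part of their known subpopulations are marked `coverage = "partial"`.
#'
#' @return A tibble with one row per species and the columns of
#'   [account_species()] output.
#' @export
#' @examples
#' res <- fixture_results()
#' res[which.max(res$T), c("scientific_name", "T_percent")]
fixture_results <- function() {
  t2 <- load_fixtures()$table2
  t2 |>
    dplyr::transmute(
      species_id = gsub(" ", "_", tolower(.data$scientific_name)),
      scientific_name = .data$scientific_name,
      common_name = .data$common_name,
      threat_status = .data$threat_status,
      global_population = .data$global_population,
      n_subpops_used = .data$n_subpops,
      protected_total = NA_real_,
      tourism_protected = .data$sr,
      T = .data$sr / .data$global_population,
      T_percent = render_T_percent(.data$T),
      coverage = dplyr::if_else(
        .data$scientific_name %in% partial_coverage_species,
        "partial", "complete"
      )
    )
}
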