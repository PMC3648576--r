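stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    abort(sprintf("stage %s: %s", name, conditionMessage(e)),
          class = class(e)[1], parent = e)
  })
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
}

provenance <- function(config) {
  list(
    package = "tourishare",
    version = as.character(packageVersion("tourishare")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config
  )
}

# Funnel for results that arrive without raw occurrence records (the bundled
# reference table prints only per-species aggregates): single-PA membership is
# approximated by the count of subpopulations used.
funnel_from_results <- function(results) {
  results |>
    dplyr::group_by(.data$threat_status) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_unprotected = sum(.data$n_subpops_used == 0),
      n_single_pa = sum(.data$n_subpops_used == 1),
      n_multi_pa = sum(.data$n_subpops_used >= 2),
      n_with_T = sum(.data$coverage != "none"),
      n_partial = sum(.data$coverage == "partial"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$threat_status)
}

#' Run the full accounting pipeline and write its artifacts
#'
#' Reads (or loads) the inputs, runs per-species accounting, summaries and
#' the inferential layer, and writes `results.csv`, `summary.json` (funnel,
#' bins, top reserves), `stats.json` (group comparison and regression) and
#' `provenance.json` into `out`.
#'
#' @param species,subpopulations,protected_areas,country_revenue Paths to the
#'   four input CSVs; ignored when `fixtures = TRUE` or `world` is given.
#' @param world Optionally, an in-memory `tourism_world`.
#' @param fixtures If `TRUE`, run on the bundled reference species table
#'   instead of external inputs.
#' @param out Output directory, created if needed.
#' @param test_variant,regression_variant Passed to [compare_groups()] and
#'   [regress_T_on_G()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `results`, `funnel`, `bins`, `comparison`,
#'   `regression` and the paths written.
#' @export
run_compute <- function(species = NULL, subpopulations = NULL,
                        protected_areas = NULL, country_revenue = NULL,
                        world = NULL, fixtures = FALSE, out,
                        test_variant = c("pooled", "unequal"),
                        regression_variant = c("arcsine", "loglog", "log1p_percent"),
                        quiet = FALSE) {
  test_variant <- match.arg(test_variant)
  regression_variant <- match.arg(regression_variant)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  if (fixtures) {
    results <- stage("fixtures", fixture_results())
    say("loaded bundled reference table: %d species", nrow(results))
    funnel <- stage("summaries", funnel_from_results(results))
  } else {
    if (is.null(world)) {
      world <- stage("read", read_world(species, subpopulations,
                                        protected_areas, country_revenue))
    }
    say("inputs: %d species, %d subpopulation records, %d protected areas, %d countries with revenue",
        nrow(world$species), nrow(world$subpopulations),
        nrow(world$protected_areas), nrow(world$country_revenue))
    results <- stage("accounting", account_species(world))
    say("accounting: %d species with computable T (%d partial, %d without)",
        sum(results$coverage != "none"), sum(results$coverage == "partial"),
        sum(results$coverage == "none"))
    funnel <- stage("summaries", coverage_funnel(world$species,
                                                 world$subpopulations, results))
  }

  bins <- stage("summaries", bin_T(results))
  top_pas <- if (!fixtures && !is.null(world)) {
    utils::head(species_per_pa(world$subpopulations), 20)
  } else {
    NULL
  }

  with_T <- dplyr::filter(results, .data$coverage != "none")
  comparison <- tryCatch(
    stage("stats", compare_groups(results, variant = test_variant)),
    tourishare_insufficient_data_error = function(e) NULL
  )
  regression <- tryCatch(
    stage("stats", regress_T_on_G(results, variant = regression_variant)),
    tourishare_insufficient_data_error = function(e) NULL,
    tourishare_singular_fit_error = function(e) NULL
  )

  results_path <- file.path(out, "results.csv")
  write_results(results, results_path)

  summary_doc <- list(
    n_species = nrow(results),
    n_with_T = nrow(with_T),
    funnel = funnel,
    bins = tibble::as_tibble(bins),
    top_protected_areas = top_pas
  )
  write_json_file(summary_doc, file.path(out, "summary.json"))

  stats_doc <- list(
    configuration = list(test_variant = test_variant,
                         regression_variant = regression_variant,
                         transform = "arcsine square-root of T as a proportion"),
    group_comparison = if (!is.null(comparison)) {
      list(groups = comparison$groups, t_statistic = comparison$t_statistic,
           degrees_freedom = comparison$degrees_freedom,
           p_value = comparison$p_value)
    },
    regression = if (!is.null(regression)) {
      glance(regression)
    }
  )
  write_json_file(stats_doc, file.path(out, "stats.json"))
  write_json_file(provenance(list(fixtures = fixtures,
                                  test_variant = test_variant,
                                  regression_variant = regression_variant)),
                  file.path(out, "provenance.json"))
  say("wrote %s", out)
  invisible(list(results = results, funnel = funnel, bins = bins,
                 comparison = comparison, regression = regression,
                 paths = file.path(out, c("results.csv", "summary.json",
                                          "stats.json", "provenance.json"))))
}

#' Generate a synthetic world and write it to disk
#'
#' Writes the four input CSVs, `ground_truth.csv`, the configuration as a
#' flat `config.txt` (key=value lines) and `provenance.json`. Output is
#' byte-identical across runs with the same configuration.
#'
#' @param config A [generator_config()].
#' @param out Output directory, created if needed.
#' @return Invisibly, the generated `synthetic_world`.
#' @export
run_simulate <- function(config = generator_config(), out) {
  validate_config(config)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  world <- generate_world(config)
  write_world(world, out)
  keys <- vapply(config, function(v) paste(format(v, digits = 15), collapse = ","),
                 character(1))
  writeLines(paste0(names(keys), "=", keys), file.path(out, "config.txt"))
  write_json_file(provenance(unclass(config)), file.path(out, "provenance.json"))
  invisible(world)
}
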