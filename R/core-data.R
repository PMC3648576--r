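#' Input data model
#'
#' The analysis consumes four tables:
#'
#' * **species** — one row per threatened species: `species_id`,
#'   `scientific_name`, `common_name`, `threat_status` (`"CR"` or `"EN"`),
#'   `global_population` (the point global population G, at least 1),
#'   optional informational bounds `pop_low`/`pop_high`, and a logical
#'   `migratory` flag.
#' * **subpopulations** — one row per species-by-protected-area record:
#'   `species_id`, `pa_id`, `size` (individuals inside the area, S_n, may be
#'   zero), `occupancy` (`"resident"`, `"breeding"`, or `"nonbreeding"`).
#' * **protected_areas** — `pa_id`, `name`, `country_code`, `tenure`
#'   (`"public"`, `"communal"`, `"private"`, `"other"`), and an optional
#'   site-level `revenue_share_override` in \[0, 1\] (used e.g. for private
#'   reserves fully funded by tourism).
#' * **country_revenue** — one row per country: `country_code` and
#'   `revenue_share`, the national-scale proportion R of protected-area
#'   budgets derived from tourism, in \[0, 1\], plus a free-text `source`.
#'
#' Revenue shares are stored as proportions in \[0, 1\] everywhere inside the
#' package; percentages appear only in rendered reports.
#'
#' @name data-model
#' @keywords internal
NULL

threat_levels <- c("CR", "EN")
occupancy_levels <- c("resident", "breeding", "nonbreeding")
tenure_levels <- c("public", "communal", "private", "other")

species_cols <- c(
  "species_id", "scientific_name", "common_name", "threat_status",
  "global_population", "pop_low", "pop_high", "migratory"
)
subpop_cols <- c("species_id", "pa_id", "size", "occupancy")
pa_cols <- c("pa_id", "name", "country_code", "tenure", "revenue_share_override")
revenue_cols <- c("country_code", "revenue_share", "source")

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort_schema(
      sprintf(
        "%s table is missing required column%s: %s",
        what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
      ),
      missing_columns = missing
    )
  }
  invisible(df)
}

check_enum <- function(x, levels, what, table) {
  bad <- setdiff(unique(x[!is.na(x)]), levels)
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "%s table: %s must be one of {%s}; found: %s",
      table, what, paste(levels, collapse = ", "), paste(bad, collapse = ", ")
    ))
  }
}

check_proportion <- function(x, what, table, allow_na = TRUE) {
  ok <- is.na(x) | (x >= 0 & x <= 1)
  if (!allow_na && anyNA(x)) {
    abort_validation(sprintf("%s table: %s must not be missing", table, what))
  }
  if (!all(ok)) {
    abort_validation(sprintf(
      "%s table: %s must lie in [0, 1]; found value(s) outside: %s",
      table, what, paste(format(x[!ok][seq_len(min(3, sum(!ok)))]), collapse = ", ")
    ))
  }
}

check_count <- function(x, what, table, min = 0) {
  bad <- !is.na(x) & x < min
  if (any(bad)) {
    abort_validation(sprintf(
      "%s table: %s must be >= %s; found %s",
      table, what, min, paste(format(x[bad][seq_len(min(3, sum(bad)))]), collapse = ", ")
    ))
  }
}

check_unique <- function(keys, what, table) {
  dup <- duplicated(keys)
  if (any(dup)) {
    abort_integrity(sprintf(
      "%s table: duplicate %s: %s",
      table, what, paste(unique(keys[dup])[seq_len(min(3, length(unique(keys[dup]))))], collapse = ", ")
    ))
  }
}

#' Validate the four input tables and assemble a world object
#'
#' Checks every type invariant of the data model (enumerations, counts,
#' proportions, key uniqueness) and referential integrity: each
#' subpopulation's `species_id` and `pa_id` must resolve, while a protected
#' area whose `country_code` has no row in the revenue table is *flagged*,
#' not rejected — missing national revenue data is an expected feature of the
#' data and handled downstream as partial coverage.
#'
#' @param species,subpopulations,protected_areas,country_revenue Data frames
#'   following the schemas in [data-model].
#' @return A list of the four validated tibbles with class `tourism_world`.
#'   Countries present on protected areas but absent from the revenue table
#'   are recorded in `attr(world, "unresolved_countries")`.
#' @export
#' @examples
#' w <- generate_world(generator_config(seed = 1, n_species = 20))
#' validate_world(w$species, w$subpopulations, w$protected_areas, w$country_revenue)
validate_world <- function(species, subpopulations, protected_areas, country_revenue) {
  check_columns(species, species_cols, "species")
  check_columns(subpopulations, subpop_cols, "subpopulations")
  check_columns(protected_areas, pa_cols, "protected_areas")
  check_columns(country_revenue, revenue_cols, "country_revenue")

  species <- tibble::as_tibble(species)
  subpopulations <- tibble::as_tibble(subpopulations)
  protected_areas <- tibble::as_tibble(protected_areas)
  country_revenue <- tibble::as_tibble(country_revenue)

  check_unique(species$species_id, "species_id", "species")
  check_enum(species$threat_status, threat_levels, "threat_status", "species")
  check_count(species$global_population, "global_population", "species", min = 1)
  if (anyNA(species$global_population)) {
    abort_validation("species table: global_population must not be missing")
  }
  bounds_bad <- !is.na(species$pop_low) & !is.na(species$pop_high) &
    (species$pop_low > species$global_population |
       species$global_population > species$pop_high)
  if (any(bounds_bad)) {
    abort_validation(sprintf(
      "species table: population bounds must satisfy pop_low <= global_population <= pop_high (violated for %s)",
      paste(species$species_id[bounds_bad][seq_len(min(3, sum(bounds_bad)))], collapse = ", ")
    ))
  }

  check_unique(paste(subpopulations$species_id, subpopulations$pa_id, sep = "\r"),
               "(species_id, pa_id) pairs", "subpopulations")
  check_count(subpopulations$size, "size", "subpopulations", min = 0)
  check_enum(subpopulations$occupancy, occupancy_levels, "occupancy", "subpopulations")

  check_unique(protected_areas$pa_id, "pa_id", "protected_areas")
  check_enum(protected_areas$tenure, tenure_levels, "tenure", "protected_areas")
  check_proportion(protected_areas$revenue_share_override, "revenue_share_override",
                   "protected_areas")

  check_unique(country_revenue$country_code, "country_code", "country_revenue")
  check_proportion(country_revenue$revenue_share, "revenue_share",
                   "country_revenue", allow_na = FALSE)

  orphan_sp <- setdiff(subpopulations$species_id, species$species_id)
  if (length(orphan_sp) > 0) {
    abort_integrity(sprintf(
      "subpopulations reference unknown species_id: %s",
      paste(orphan_sp[seq_len(min(3, length(orphan_sp)))], collapse = ", ")
    ))
  }
  orphan_pa <- setdiff(subpopulations$pa_id, protected_areas$pa_id)
  if (length(orphan_pa) > 0) {
    abort_integrity(sprintf(
      "subpopulations reference unknown pa_id: %s",
      paste(orphan_pa[seq_len(min(3, length(orphan_pa)))], collapse = ", ")
    ))
  }

  unresolved <- setdiff(protected_areas$country_code, country_revenue$country_code)

  world <- structure(
    list(
      species = species,
      subpopulations = subpopulations,
      protected_areas = protected_areas,
      country_revenue = country_revenue
    ),
    unresolved_countries = unresolved,
    class = c("tourism_world", "list")
  )
  world
}

#' @export
print.tourism_world <- function(x, ...) {
  cat(sprintf(
    "<tourism_world> %d species, %d subpopulation records, %d protected areas, %d countries with revenue data\n",
    nrow(x$species), nrow(x$subpopulations), nrow(x$protected_areas),
    nrow(x$country_revenue)
  ))
  unresolved <- attr(x, "unresolved_countries")
  if (length(unresolved) > 0) {
    cat(sprintf("  countries without revenue data: %s\n",
                paste(unresolved, collapse = ", ")))
  }
  invisible(x)
}

species_col_types <- readr::cols(
  species_id = readr::col_character(),
  scientific_name = readr::col_character(),
  common_name = readr::col_character(),
  threat_status = readr::col_character(),
  global_population = readr::col_double(),
  pop_low = readr::col_double(),
  pop_high = readr::col_double(),
  migratory = readr::col_logical()
)
subpop_col_types <- readr::cols(
  species_id = readr::col_character(),
  pa_id = readr::col_character(),
  size = readr::col_double(),
  occupancy = readr::col_character()
)
pa_col_types <- readr::cols(
  pa_id = readr::col_character(),
  name = readr::col_character(),
  country_code = readr::col_character(),
  tenure = readr::col_character(),
  revenue_share_override = readr::col_double()
)
revenue_col_types <- readr::cols(
  country_code = readr::col_character(),
  revenue_share = readr::col_double(),
  source = readr::col_character()
)

read_one <- function(path, col_types, required, what) {
  if (!file.exists(path)) {
    abort_schema(sprintf("%s file does not exist: %s", what, path))
  }
  # schema mismatches are reported by check_columns below, not by readr's
  # unmatched-parser warning
  df <- suppressWarnings(
    readr::read_csv(path, col_types = col_types, show_col_types = FALSE)
  )
  readr::stop_for_problems(df)
  check_columns(df, required, what)
  df
}

#' Read and validate the four input CSVs
#'
#' Reads the species, subpopulation, protected-area and country-revenue
#' tables (UTF-8, comma-separated, header row, `.` decimal separator) and
#' runs the full validation of [validate_world()].
#'
#' @param species,subpopulations,protected_areas,country_revenue Paths to the
#'   four CSV files.
#' @return A validated `tourism_world` (see [validate_world()]).
#' @export
read_world <- function(species, subpopulations, protected_areas, country_revenue) {
  validate_world(
    species = read_one(species, species_col_types, species_cols, "species"),
    subpopulations = read_one(subpopulations, subpop_col_types, subpop_cols,
                              "subpopulations"),
    protected_areas = read_one(protected_areas, pa_col_types, pa_cols,
                               "protected_areas"),
    country_revenue = read_one(country_revenue, revenue_col_types, revenue_cols,
                               "country_revenue")
  )
}

#' Write the four input tables of a world to CSV
#'
#' @param world A `tourism_world` (possibly with extra elements, which are
#'   ignored except `ground_truth`, written when present).
#' @param dir Output directory, created if needed.
#' @return Invisibly, a named character vector of the files written.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    species = "species.csv",
    subpopulations = "subpopulations.csv",
    protected_areas = "protected_areas.csv",
    country_revenue = "country_revenue.csv"
  )
  out <- character(0)
  for (nm in names(files)) {
    path <- file.path(dir, files[[nm]])
    readr::write_csv(world[[nm]], path)
    out[nm] <- path
  }
  if (!is.null(world$ground_truth)) {
    path <- file.path(dir, "ground_truth.csv")
    readr::write_csv(world$ground_truth$species, path)
    out["ground_truth"] <- path
  }
  invisible(out)
}

#' Write per-species accounting results to CSV
#'
#' Columns mirror the published per-species table: threat status, global
#' population G, number of subpopulations used, the tourism-protected count
#' SR rounded to an integer, and T as a one-decimal percentage. Rows are
#' sorted by T (full precision) descending, ties broken alphabetically by
#' scientific name.
#'
#' @param results Accounting results from [account_species()] (or
#'   [fixture_results()]).
#' @param path Output CSV path.
#' @return Invisibly, the tibble that was written.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  out <- results |>
    dplyr::arrange(dplyr::desc(.data$T), .data$scientific_name) |>
    dplyr::transmute(
      species_id = .data$species_id,
      scientific_name = .data$scientific_name,
      threat_status = .data$threat_status,
      global_population = .data$global_population,
      n_subpops_used = .data$n_subpops_used,
      sr = round_half_up(.data$tourism_protected, 0),
      t_percent = .data$T_percent,
      coverage = .data$coverage
    )
  readr::write_csv(out, path)
  invisible(out)
}

#' Read back a results CSV written by [write_results()]
#'
#' @param path Path to the results CSV.
#' @return A tibble with the written columns.
#' @export
read_results <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    species_id = readr::col_character(),
    scientific_name = readr::col_character(),
    threat_status = readr::col_character(),
    global_population = readr::col_double(),
    n_subpops_used = readr::col_double(),
    sr = readr::col_double(),
    t_percent = readr::col_double(),
    coverage = readr::col_character()
  ), show_col_types = FALSE)
}
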