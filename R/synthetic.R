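#' Configuration for the synthetic world generator
#'
#' Defaults emulate the scale and shape of the compiled bird data: 562
#' candidate species of which 190 are critically endangered, roughly 43%
#' with no protected-area record at all, protected species occurring in a
#' handful (mostly 1-6) of areas, 77 range countries, and national tourism
#' revenue shares mostly between 5% and 80% with a zero-inflation atom and a
#' fraction of countries lacking revenue data altogether.
#'
#' @param seed Integer seed governing all randomness.
#' @param n_species Number of candidate species.
#' @param cr_fraction Fraction classified CR (exact count, `round(n *
#'   cr_fraction)`); the rest are EN.
#' @param n_countries Number of countries.
#' @param revenue_beta_params Shape parameters of the Beta distribution of
#'   national revenue shares on \[0, 1\].
#' @param zero_revenue_fraction Probability a country with revenue data has
#'   R = 0.
#' @param pas_per_country_mean Mean protected areas per country (each country
#'   gets at least one).
#' @param unprotected_fraction Fraction of species with no subpopulation
#'   records (exact count).
#' @param subpops_per_species_mean Mean subpopulations per protected species
#'   (at least one each).
#' @param protected_fraction_of_G Interval from which each protected species'
#'   total protected fraction of G is drawn uniformly.
#' @param migratory_fraction Probability a species is migratory.
#' @param missing_revenue_fraction Probability a country is absent from the
#'   revenue table (its areas resolve to missing R).
#' @param status_effect Additive shift applied to CR species' protected
#'   fraction (clamped to \[0, 1\]); 0 gives a null world with no
#'   between-status difference.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_species = 562,
                             cr_fraction = 190 / 562,
                             n_countries = 77,
                             revenue_beta_params = c(1.5, 3.5),
                             zero_revenue_fraction = 0.08,
                             pas_per_country_mean = 520 / 77,
                             unprotected_fraction = 241 / 562,
                             subpops_per_species_mean = 1.45,
                             protected_fraction_of_G = c(0.02, 0.6),
                             migratory_fraction = 0.2,
                             missing_revenue_fraction = 0.18,
                             status_effect = 0) {
  cfg <- list(
    seed = as.integer(seed), n_species = n_species, cr_fraction = cr_fraction,
    n_countries = n_countries, revenue_beta_params = revenue_beta_params,
    zero_revenue_fraction = zero_revenue_fraction,
    pas_per_country_mean = pas_per_country_mean,
    unprotected_fraction = unprotected_fraction,
    subpops_per_species_mean = subpops_per_species_mean,
    protected_fraction_of_G = protected_fraction_of_G,
    migratory_fraction = migratory_fraction,
    missing_revenue_fraction = missing_revenue_fraction,
    status_effect = status_effect
  )
  validate_config(cfg)
  structure(cfg, class = c("generator_config", "list"))
}

validate_config <- function(cfg) {
  chk_prop <- function(name) {
    v <- cfg[[name]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      abort_config(sprintf("config: %s must be a proportion in [0, 1]", name))
    }
  }
  for (nm in c("cr_fraction", "zero_revenue_fraction", "unprotected_fraction",
               "migratory_fraction", "missing_revenue_fraction")) {
    chk_prop(nm)
  }
  if (cfg$n_species < 1 || cfg$n_countries < 1) {
    abort_config("config: n_species and n_countries must be >= 1")
  }
  if (cfg$pas_per_country_mean <= 0 || cfg$subpops_per_species_mean < 1) {
    abort_config("config: pas_per_country_mean must be > 0 and subpops_per_species_mean >= 1")
  }
  if (any(cfg$revenue_beta_params <= 0) || length(cfg$revenue_beta_params) != 2) {
    abort_config("config: revenue_beta_params must be two positive shapes")
  }
  pf <- cfg$protected_fraction_of_G
  if (length(pf) != 2 || pf[1] > pf[2] || pf[1] < 0 || pf[2] > 1) {
    abort_config("config: protected_fraction_of_G must be a non-empty interval inside [0, 1]")
  }
  invisible(cfg)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate a synthetic world with known ground truth
#'
#' Builds a complete, internally consistent set of the four input tables plus
#' the generator's own bookkeeping: per-subpopulation resolved revenue shares
#' and per-species true T and coverage class, so every pipeline stage can be
#' checked against construction. The total protected count of each species is
#' drawn as a fraction of G and then partitioned across its subpopulations,
#' so the accounting precondition `sum(S) <= G` holds by construction.
#' Migratory species' countable subpopulations are breeding records,
#' non-migratory species' are resident records; a quarter of protected
#' species also receive one non-countable decoy record to exercise the
#' eligibility filter.
#'
#' @param config A [generator_config()].
#' @return A `synthetic_world` (also a valid `tourism_world`) with elements
#'   `species`, `subpopulations`, `protected_areas`, `country_revenue`,
#'   `ground_truth` (list of `species` and `subpopulations` truth tibbles)
#'   and `config`.
#' @export
#' @examples
#' w <- generate_world(generator_config(seed = 42, n_species = 50))
#' w$ground_truth$species[1:3, c("species_id", "true_T", "coverage")]
generate_world <- function(config = generator_config()) {
  validate_config(config)
  with_seed(config$seed, {
    # --- countries and revenue ------------------------------------------
    country_code <- sprintf("C%03d", seq_len(config$n_countries))
    has_revenue <- stats::runif(config$n_countries) >= config$missing_revenue_fraction
    r_val <- ifelse(
      stats::runif(config$n_countries) < config$zero_revenue_fraction,
      0,
      stats::rbeta(config$n_countries, config$revenue_beta_params[1],
                   config$revenue_beta_params[2])
    )
    country_revenue <- tibble::tibble(
      country_code = country_code[has_revenue],
      revenue_share = r_val[has_revenue],
      source = "synthetic"
    )

    # --- protected areas -------------------------------------------------
    n_pas_per_country <- 1L + stats::rpois(config$n_countries,
                                           max(config$pas_per_country_mean - 1, 0))
    pa_country <- rep(country_code, n_pas_per_country)
    n_pas <- length(pa_country)
    pa_id <- sprintf("PA%04d", seq_len(n_pas))
    tenure <- sample(tenure_levels, n_pas, replace = TRUE,
                     prob = c(0.78, 0.08, 0.10, 0.04))
    # private reserves fully funded by tourism carry a site override; they
    # share the zero-inflation regime so a no-tourism-revenue world stays one
    override_value <- ifelse(stats::runif(n_pas) < config$zero_revenue_fraction, 0, 1)
    override <- ifelse(tenure == "private" & stats::runif(n_pas) < 0.5,
                       override_value, NA_real_)
    protected_areas <- tibble::tibble(
      pa_id = pa_id, name = paste("Synthetic Reserve", seq_len(n_pas)),
      country_code = pa_country, tenure = tenure,
      revenue_share_override = override
    )

    # --- species ----------------------------------------------------------
    n_sp <- config$n_species
    species_id <- sprintf("SP%04d", seq_len(n_sp))
    n_cr <- round(n_sp * config$cr_fraction)
    status <- rep("EN", n_sp)
    status[sample.int(n_sp, n_cr)] <- "CR"
    G <- pmax(50, round(stats::rlnorm(n_sp, meanlog = log(2000), sdlog = 1.5)))
    has_bounds <- stats::runif(n_sp) < 0.4
    pop_low <- ifelse(has_bounds, floor(G * stats::runif(n_sp, 0.5, 1)), NA_real_)
    pop_high <- ifelse(has_bounds, ceiling(G * stats::runif(n_sp, 1, 2)), NA_real_)
    migratory <- stats::runif(n_sp) < config$migratory_fraction
    species <- tibble::tibble(
      species_id = species_id,
      scientific_name = sprintf("Avis ficta%04d", seq_len(n_sp)),
      common_name = sprintf("Synthetic Bird %04d", seq_len(n_sp)),
      threat_status = status, global_population = G,
      pop_low = pop_low, pop_high = pop_high, migratory = migratory
    )

    # --- subpopulations ---------------------------------------------------
    n_unprot <- round(n_sp * config$unprotected_fraction)
    unprotected <- logical(n_sp)
    unprotected[sample.int(n_sp, n_unprot)] <- TRUE
    prot_idx <- which(!unprotected)

    k <- 1L + stats::rpois(length(prot_idx),
                           config$subpops_per_species_mean - 1)
    k <- pmin(k, n_pas)
    pf <- stats::runif(length(prot_idx), config$protected_fraction_of_G[1],
                       config$protected_fraction_of_G[2]) +
      config$status_effect * (status[prot_idx] == "CR")
    pf <- pmin(pmax(pf, 0), 1)
    total <- floor(pf * G[prot_idx])

    sp_row <- rep(seq_along(prot_idx), k)
    sub_pa <- unlist(lapply(k, function(ki) sample.int(n_pas, ki)))
    w <- stats::rgamma(length(sp_row), shape = 1)
    w_tot <- stats::ave(w, sp_row, FUN = sum)
    size <- floor(total[sp_row] * w / w_tot)
    sp_idx <- prot_idx[sp_row]
    occupancy <- ifelse(migratory[sp_idx], "breeding", "resident")

    eligible_subpops <- tibble::tibble(
      species_id = species_id[sp_idx],
      pa_id = pa_id[sub_pa],
      size = size,
      occupancy = occupancy,
      eligible = TRUE
    )

    # decoy records with non-countable occupancy, in areas not already used
    decoy_sp <- prot_idx[stats::runif(length(prot_idx)) < 0.25]
    decoys <- purrr::map_dfr(decoy_sp, function(i) {
      used <- sub_pa[sp_idx == i]
      free <- setdiff(seq_len(n_pas), used)
      if (length(free) == 0) return(NULL)
      tibble::tibble(
        species_id = species_id[i],
        pa_id = pa_id[sample(free, 1)],
        size = floor(stats::runif(1) * 0.1 * G[i]),
        occupancy = if (migratory[i]) {
          sample(c("resident", "nonbreeding"), 1)
        } else {
          sample(c("breeding", "nonbreeding"), 1)
        },
        eligible = FALSE
      )
    })
    all_subpops <- dplyr::bind_rows(eligible_subpops, decoys)

    # --- ground truth ------------------------------------------------------
    resolved <- resolve_revenue_share(protected_areas, country_revenue)
    gt_sub <- all_subpops |>
      dplyr::left_join(resolved, by = "pa_id") |>
      dplyr::rename(resolved_R = "revenue_share")

    gt_species <- gt_sub |>
      dplyr::filter(.data$eligible) |>
      dplyr::group_by(.data$species_id) |>
      dplyr::summarise(
        n_eligible = dplyr::n(),
        n_used = sum(!is.na(.data$resolved_R)),
        true_SR = sum(.data$size * .data$resolved_R, na.rm = TRUE),
        .groups = "drop"
      )
    gt_species <- species |>
      dplyr::select("species_id", "threat_status", "global_population") |>
      dplyr::left_join(gt_species, by = "species_id") |>
      dplyr::mutate(
        n_eligible = dplyr::coalesce(.data$n_eligible, 0L),
        n_used = dplyr::coalesce(.data$n_used, 0L),
        true_SR = dplyr::coalesce(.data$true_SR, 0),
        true_T = .data$true_SR / .data$global_population,
        coverage = dplyr::case_when(
          .data$n_used == 0 ~ "none",
          .data$n_used < .data$n_eligible ~ "partial",
          TRUE ~ "complete"
        )
      )

    world <- validate_world(
      species = species,
      subpopulations = dplyr::select(all_subpops, -"eligible"),
      protected_areas = protected_areas,
      country_revenue = country_revenue
    )
    world$ground_truth <- list(species = gt_species, subpopulations = gt_sub)
    world$config <- config
    class(world) <- c("synthetic_world", class(world))
    world
  })
}

#' Funnel counts from the generator's own bookkeeping
#'
#' Computes the coverage funnel directly from a synthetic world's ground
#' truth, in the same shape as [coverage_funnel()], for end-to-end
#' comparison against the pipeline.
#'
#' @param world A `synthetic_world` from [generate_world()].
#' @return A tibble with one row per threat status.
#' @export
funnel_truth <- function(world) {
  if (is.null(world$ground_truth)) {
    abort_validation("funnel_truth needs a synthetic world with ground truth")
  }
  n_pas_rec <- world$ground_truth$subpopulations |>
    dplyr::distinct(.data$species_id, .data$pa_id) |>
    dplyr::count(.data$species_id, name = "n_pas")
  world$ground_truth$species |>
    dplyr::left_join(n_pas_rec, by = "species_id") |>
    dplyr::mutate(n_pas = dplyr::coalesce(.data$n_pas, 0L)) |>
    dplyr::group_by(.data$threat_status) |>
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
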