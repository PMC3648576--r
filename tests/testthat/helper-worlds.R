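# Hand-built micro-worlds used across the suite.

tiny_species <- function(ids, G, status = "EN", migratory = FALSE) {
  tibble::tibble(
    species_id = ids,
    scientific_name = paste("Avis", ids),
    common_name = paste("Bird", ids),
    threat_status = rep_len(status, length(ids)),
    global_population = rep_len(G, length(ids)),
    pop_low = NA_real_, pop_high = NA_real_,
    migratory = rep_len(migratory, length(ids))
  )
}

tiny_pas <- function(ids, country = "AA", tenure = "public", override = NA_real_) {
  tibble::tibble(
    pa_id = ids,
    name = paste("Reserve", ids),
    country_code = rep_len(country, length(ids)),
    tenure = rep_len(tenure, length(ids)),
    revenue_share_override = rep_len(override, length(ids))
  )
}

tiny_subpops <- function(species_id, pa_id, size, occupancy = "resident") {
  tibble::tibble(
    species_id = species_id, pa_id = pa_id, size = size,
    occupancy = rep_len(occupancy, length(species_id))
  )
}

tiny_revenue <- function(codes, shares) {
  tibble::tibble(country_code = codes, revenue_share = shares,
                 source = "test")
}

# One species, two subpopulations with distinct country revenue shares:
# S = (100, 50), R = (0.2, 0.4), G = 1000 => sum(S*R) = 40, T = 0.04.
two_subpop_world <- function() {
  validate_world(
    species = tiny_species("sp1", G = 1000),
    subpopulations = tiny_subpops(c("sp1", "sp1"), c("pa1", "pa2"), c(100, 50)),
    protected_areas = dplyr::bind_rows(tiny_pas("pa1", country = "AA"),
                                       tiny_pas("pa2", country = "BB")),
    country_revenue = tiny_revenue(c("AA", "BB"), c(0.2, 0.4))
  )
}

tiny_results_row <- function(id, sci, T, G = 1000, status = "EN") {
  tibble::tibble(
    species_id = id, scientific_name = sci, common_name = sci,
    threat_status = status, global_population = G,
    n_subpops_used = 1L, protected_total = T * G, tourism_protected = T * G,
    T = T, T_percent = render_T_percent(T), coverage = "complete"
  )
}

# Independent term-by-term evaluation of sum(S_n * R_n) / G used as the
# accounting oracle: a plain loop, no joins, no grouping.
brute_force_T <- function(G, sizes, shares) {
  acc <- 0
  for (i in seq_along(sizes)) {
    if (!is.na(shares[i])) acc <- acc + sizes[i] * shares[i]
  }
  acc / G
}
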