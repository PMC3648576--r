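test_that("eligibility filter keeps resident records for sedentary species and breeding records for migrants", {
  species <- dplyr::bind_rows(
    tiny_species("sed", G = 100, migratory = FALSE),
    tiny_species("mig", G = 100, migratory = TRUE)
  )
  subs <- tibble::tibble(
    species_id = c("sed", "sed", "sed", "mig", "mig", "mig"),
    pa_id = paste0("pa", 1:6),
    size = rep(10, 6),
    occupancy = c("resident", "breeding", "nonbreeding",
                  "resident", "breeding", "nonbreeding")
  )
  kept <- filter_eligible(subs, species)
  expect_equal(kept$pa_id, c("pa1", "pa5"))
  expect_equal(kept$occupancy, c("resident", "breeding"))
  # order preserved, empty in -> empty out
  expect_equal(nrow(filter_eligible(subs[0, ], species)), 0)
})

test_that("revenue resolution prefers site overrides, falls back to national share, and treats missing as a value", {
  pas <- dplyr::bind_rows(
    tiny_pas("private", country = "SC", tenure = "private", override = 1.0),
    tiny_pas("park_ca", country = "CA"),
    tiny_pas("no_data", country = "XX")
  )
  revenue <- tiny_revenue(c("SC", "CA"), c(0.3, 0.14))
  r <- resolve_revenue_share(pas, revenue)
  expect_equal(r$revenue_share[r$pa_id == "private"], 1.0)
  expect_equal(r$revenue_share[r$pa_id == "park_ca"], 0.14)
  expect_true(is.na(r$revenue_share[r$pa_id == "no_data"]))
})

test_that("account_species evaluates T = sum(S*R)/G with the documented coverage classes", {
  w <- two_subpop_world()
  res <- account_species(w)
  expect_equal(res$tourism_protected, 40)   # 100*0.2 + 50*0.4
  expect_equal(res$T, 0.04)
  expect_equal(res$coverage, "complete")
  expect_equal(res$n_subpops_used, 2L)
  expect_equal(res$protected_total, 150)

  # all resolvable R = 0 -> T = 0 with complete coverage
  zero <- validate_world(
    species = tiny_species("sp1", G = 1000),
    subpopulations = tiny_subpops(c("sp1", "sp1"), c("pa1", "pa2"), c(100, 50)),
    protected_areas = dplyr::bind_rows(tiny_pas("pa1"), tiny_pas("pa2")),
    country_revenue = tiny_revenue("AA", 0)
  )
  zres <- account_species(zero)
  expect_equal(zres$T, 0)
  expect_equal(zres$coverage, "complete")

  # one resolvable and one unresolvable area -> partial coverage,
  # missing R excluded from the numerator
  part <- validate_world(
    species = tiny_species("sp1", G = 1000),
    subpopulations = tiny_subpops(c("sp1", "sp1"), c("pa1", "pa2"), c(100, 50)),
    protected_areas = dplyr::bind_rows(tiny_pas("pa1", country = "AA"),
                                       tiny_pas("pa2", country = "XX")),
    country_revenue = tiny_revenue("AA", 0.2)
  )
  pres <- account_species(part)
  expect_equal(pres$tourism_protected, 20)
  expect_equal(pres$coverage, "partial")
  expect_equal(pres$n_subpops_used, 1L)

  # no resolvable subpopulation at all -> coverage none, excluded downstream
  none <- validate_world(
    species = tiny_species("sp1", G = 1000),
    subpopulations = tiny_subpops("sp1", "pa1", 100),
    protected_areas = tiny_pas("pa1", country = "XX"),
    country_revenue = tiny_revenue("AA", 0.2)
  )
  nres <- account_species(none)
  expect_equal(nres$coverage, "none")
  expect_equal(nres$n_subpops_used, 0L)

  # used subpopulations exceeding G is a data inconsistency naming the species
  over <- validate_world(
    species = tiny_species("sp1", G = 100),
    subpopulations = tiny_subpops("sp1", "pa1", 500),
    protected_areas = tiny_pas("pa1"),
    country_revenue = tiny_revenue("AA", 0.2)
  )
  err <- expect_error(account_species(over), class = "tourishare_data_error")
  expect_match(conditionMessage(err), "sp1")
})

test_that("T percentages render at one decimal, half away from zero, matching published rows", {
  expect_equal(render_T_percent(114 / 178), 64.0)
  expect_equal(render_T_percent(77 / 1220000), 0.0)
  expect_equal(render_T_percent(18 / 663), 2.7)
  expect_equal(render_T_percent(26040 / 52000), 50.1)
  # exact decimal halfway cases round away from zero
  expect_equal(render_T_percent(87 / 2000), 4.4)
  expect_equal(render_T_percent(18 / 2400), 0.8)
  expect_equal(round_half_up(-4.35, 1), -4.4)
  # domain is enforced
  expect_error(render_T_percent(1.2), class = "tourishare_validation_error")
  expect_error(render_T_percent(-0.1), class = "tourishare_validation_error")
})

test_that("accounting matches brute-force term-by-term evaluation on random small instances", {
  set.seed(402)
  for (rep in 1:40) {
    n_sub <- sample(0:6, 1)
    G <- sample(100:100000, 1)
    sizes <- if (n_sub > 0) sample(0:floor(G / max(n_sub, 1)), n_sub) else integer(0)
    shares <- if (n_sub > 0) round(runif(n_sub), 3) else numeric(0)
    missing <- if (n_sub > 0) runif(n_sub) < 0.2 else logical(0)

    species <- tiny_species("sp", G = G)
    pas <- tiny_pas(paste0("pa", seq_len(n_sub)),
                    country = as.character(ifelse(missing, "XX",
                                                  paste0("C", seq_len(n_sub)))))
    revenue <- tiny_revenue(paste0("C", seq_len(n_sub)), shares)
    subs <- tiny_subpops(rep("sp", n_sub), paste0("pa", seq_len(n_sub)), sizes)

    res <- account_species(species, subs, pas, revenue)
    expected <- brute_force_T(G, sizes, ifelse(missing, NA, shares))
    expect_equal(res$T, expected)
    expect_equal(res$T_percent, render_T_percent(expected))
  }
})

test_that("T respects bounds, monotonicity, and permutation invariance", {
  set.seed(403)
  for (rep in 1:20) {
    n_sub <- sample(1:6, 1)
    G <- sample(500:50000, 1)
    sizes <- sample(0:floor(G / n_sub), n_sub)
    shares <- runif(n_sub)

    world_of <- function(sz, sh, order = seq_len(n_sub)) {
      validate_world(
        species = tiny_species("sp", G = G),
        subpopulations = tiny_subpops(rep("sp", n_sub),
                                      paste0("pa", order), sz[order]),
        protected_areas = tiny_pas(paste0("pa", seq_len(n_sub)),
                                   country = paste0("C", seq_len(n_sub))),
        country_revenue = tiny_revenue(paste0("C", seq_len(n_sub)), sh)
      )
    }

    base_T <- account_species(world_of(sizes, shares))$T
    expect_gte(base_T, 0)
    expect_lte(base_T, sum(sizes) / G)
    expect_lte(sum(sizes) / G, 1)

    # raising one revenue share weakly increases T
    j <- sample(n_sub, 1)
    up <- shares
    up[j] <- min(1, up[j] + 0.3)
    expect_gte(account_species(world_of(sizes, up))$T, base_T)

    # extremes: R == 1 everywhere gives sum(S)/G; R == 0 gives 0
    expect_equal(account_species(world_of(sizes, rep(1, n_sub)))$T, sum(sizes) / G)
    expect_equal(account_species(world_of(sizes, rep(0, n_sub)))$T, 0)

    # permuting subpopulation order changes nothing
    perm <- sample(n_sub)
    expect_equal(account_species(world_of(sizes, shares, order = perm))$T, base_T)
  }
})
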