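test_that("bundled reference tables load, with the documented shapes and rows", {
  fx <- load_fixtures()
  expect_equal(nrow(fx$table2), 91)
  expect_equal(nrow(fx$table1), 14)

  penguin <- dplyr::filter(fx$table2, scientific_name == "Spheniscus demersus")
  expect_equal(penguin$threat_status, "EN")
  expect_equal(penguin$global_population, 52000)
  expect_equal(penguin$n_subpops, 6)
  expect_equal(penguin$sr, 26040)
  expect_equal(penguin$t_percent, 50.1)

  galapagos <- dplyr::filter(fx$table1, reserve_name == "Galapagos National Park")
  expect_equal(galapagos$country, "Ecuador")
  expect_equal(galapagos$n_species, 8)
  expect_equal(galapagos$n_sole, 4)

  # determinism: loading twice gives identical content
  expect_identical(fx, load_fixtures())
})

test_that("every bundled species row is self-consistent: round(100*SR/G, 1) equals the printed T", {
  t2 <- load_fixtures()$table2
  expect_identical(render_T_percent(t2$sr / t2$global_population), t2$t_percent)
})

test_that("world validation enforces type invariants", {
  w <- two_subpop_world()
  expect_s3_class(w, "tourism_world")

  # proportion outside [0, 1]
  bad_rev <- tiny_revenue("AA", 1.4)
  expect_error(
    validate_world(w$species, w$subpopulations, w$protected_areas, bad_rev),
    class = "tourishare_validation_error"
  )

  # negative subpopulation size
  bad_sub <- tiny_subpops("sp1", "pa1", -5)
  expect_error(
    validate_world(w$species, bad_sub, w$protected_areas, w$country_revenue),
    class = "tourishare_validation_error"
  )

  # global population below 1
  bad_sp <- tiny_species("sp1", G = 0)
  expect_error(
    validate_world(bad_sp, w$subpopulations, w$protected_areas, w$country_revenue),
    class = "tourishare_validation_error"
  )

  # inconsistent population bounds
  bad_bounds <- tiny_species("sp1", G = 1000)
  bad_bounds$pop_low <- 2000
  bad_bounds$pop_high <- 3000
  expect_error(
    validate_world(bad_bounds, w$subpopulations, w$protected_areas, w$country_revenue),
    class = "tourishare_validation_error"
  )

  # threat status outside {CR, EN}
  bad_status <- tiny_species("sp1", G = 1000, status = "VU")
  expect_error(
    validate_world(bad_status, w$subpopulations, w$protected_areas, w$country_revenue),
    class = "tourishare_validation_error"
  )
})

test_that("world validation enforces keys and referential integrity", {
  w <- two_subpop_world()

  dup_sub <- dplyr::bind_rows(w$subpopulations, w$subpopulations[1, ])
  expect_error(
    validate_world(w$species, dup_sub, w$protected_areas, w$country_revenue),
    class = "tourishare_integrity_error"
  )

  orphan <- tiny_subpops("ghost", "pa1", 10)
  expect_error(
    validate_world(w$species, orphan, w$protected_areas, w$country_revenue),
    class = "tourishare_integrity_error"
  )

  orphan_pa <- tiny_subpops("sp1", "ghost-pa", 10)
  expect_error(
    validate_world(w$species, orphan_pa, w$protected_areas, w$country_revenue),
    class = "tourishare_integrity_error"
  )

  # a PA country without revenue data is flagged, not rejected
  pas <- dplyr::bind_rows(w$protected_areas, tiny_pas("pa3", country = "ZZ"))
  flagged <- validate_world(w$species, w$subpopulations, pas, w$country_revenue)
  expect_equal(attr(flagged, "unresolved_countries"), "ZZ")
})

test_that("read_world validates files and reports missing columns by name", {
  dir <- withr::local_tempdir()
  w <- generate_world(generator_config(seed = 11, n_species = 25, n_countries = 6))
  paths <- write_world(w, dir)

  rt <- read_world(paths["species"], paths["subpopulations"],
                   paths["protected_areas"], paths["country_revenue"])
  expect_equal(rt$species, w$species)
  expect_equal(rt$subpopulations, w$subpopulations)
  expect_equal(rt$protected_areas, w$protected_areas)
  expect_equal(rt$country_revenue, w$country_revenue)

  # header-only files give four empty tables
  for (p in paths[1:4]) {
    writeLines(readLines(p)[1], file.path(dir, basename(p)))
  }
  empty <- read_world(paths["species"], paths["subpopulations"],
                      paths["protected_areas"], paths["country_revenue"])
  expect_equal(nrow(empty$species), 0)
  expect_equal(nrow(empty$subpopulations), 0)
  expect_equal(nrow(empty$protected_areas), 0)
  expect_equal(nrow(empty$country_revenue), 0)

  # dropping a column is a schema error naming the column
  sp <- readr::read_csv(paths["species"], show_col_types = FALSE)
  readr::write_csv(dplyr::select(sp, -"migratory"), file.path(dir, "nomig.csv"))
  err <- expect_error(
    read_world(file.path(dir, "nomig.csv"), paths["subpopulations"],
               paths["protected_areas"], paths["country_revenue"]),
    class = "tourishare_schema_error"
  )
  expect_match(conditionMessage(err), "migratory")
})

test_that("write_results round-trips, orders by T descending and breaks ties alphabetically", {
  dir <- withr::local_tempdir()
  res <- fixture_results()
  path <- file.path(dir, "results.csv")
  write_results(res, path)
  back <- read_results(path)

  expect_equal(nrow(back), 91)
  expect_equal(back$scientific_name[1], "Copsychus sechellarum")
  expect_equal(back$t_percent[1], 64.0)
  # bit-exact round trip at documented precision
  ordered <- dplyr::arrange(res, dplyr::desc(T), scientific_name)
  expect_identical(back$t_percent, ordered$T_percent)
  expect_identical(back$sr, round_half_up(ordered$tourism_protected, 0))
  expect_identical(back$global_population, ordered$global_population)

  # equal T ties break alphabetically by scientific name
  tie <- dplyr::bind_rows(
    tiny_results_row("b_sp", "Zweite Art", 0.1),
    tiny_results_row("a_sp", "Erste Art", 0.1),
    tiny_results_row("c_sp", "Andere Art", 0.5)
  )
  write_results(tie, path)
  back <- read_results(path)
  expect_equal(back$scientific_name, c("Andere Art", "Erste Art", "Zweite Art"))

  # empty results give a header-only file
  write_results(res[0, ], path)
  expect_equal(nrow(read_results(path)), 0)
})
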