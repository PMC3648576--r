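Package: tourishare
Title: Tourism-Revenue Accounting for Threatened Species in Protected Areas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how much of a threatened species' global population
    is protected by tourism revenue to protected areas, using the population
    accounting statistic T = (sum of S_n * R_n) / G, where S_n are
    subpopulation sizes inside protected areas, R_n the proportion of each
    area's management budget derived from tourism, and G the species' global
    population. Provides validated CSV readers for the species /
    subpopulation / protected-area / country-revenue data model, eligibility
    filtering (resident subpopulations; breeding sites for migrants),
    national-scale revenue resolution with site-level overrides, descriptive
    summaries (T bins, species-per-reserve tables, coverage funnels),
    inferential comparisons between IUCN threat classes on the
    arcsine-square-root scale, a seeded synthetic-world generator with known
    ground truth, and bundled reference tables for critically endangered and
    endangered birds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
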