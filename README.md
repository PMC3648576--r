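# tourishare

Tourism-revenue accounting for threatened species in protected areas.

## The problem

Protected-area networks are the mainstay of conservation for threatened
birds, and in many countries a substantial share of the budget that manages
those areas comes from tourism. `tourishare` quantifies that dependency per
species with a population accounting statistic: for a species with global
population *G* and subpopulations of size *S<sub>n</sub>* inside protected
areas whose management budgets draw a proportion *R<sub>n</sub>* from
tourism,

> *T* = ( Σ<sub>n</sub> *S*<sub>n</sub> *R*<sub>n</sub> ) / *G*

is the proportion of the species' global population whose protection is
funded by tourism. The package is for conservation scientists and ecological
economists working with species–by–protected-area population tables: it
implements the eligibility rules (resident subpopulations; significant
breeding sites for migrants), national-scale revenue resolution with
site-level overrides for private reserves, the descriptive summaries
(one-decimal percentage rendering, histogram bins, species-per-reserve
tables, coverage funnels), and the inferential layer (pooled t-test of
arcsine-square-root transformed T between IUCN threat classes; OLS of
transformed T on ln *G*). A seeded synthetic-world generator with known
ground truth makes every stage testable without any external download.

The package ships the published reference tables for critically endangered
(CR) and endangered (EN) birds: the 91 species with joint *S* and *R* data
(with their aggregate tourism-protected counts *SR*) and the 14 reserves
recording four or more CR/EN species.

## Worked example

```r
library(tourishare)

res <- fixture_results()          # the 91-species reference table as accounting results
dplyr::select(res, scientific_name, threat_status, global_population,
              tourism_protected, T_percent) |> head(3)
#> 1 Copsychus sechellarum  EN    178    114  64.0
#> 2 Spheniscus demersus    EN  52000  26040  50.1
#> 3 Zosterops modestus     EN    450    178  39.6

bin_T(res)                        # histogram of rounded T percentages
#>   bin          n
#> 1 0            9
#> 2 (0,5)       41
#> 3 [5,10)      21
#> 4 [10,20)      8
#> 5 [20,100]    12

compare_groups(res)
#> Two-sample t-test on arcsine-sqrt(T) (pooled variance)
#>   group  n mean_transformed var_transformed
#> 1 CR    33            0.300          0.0314
#> 2 EN    58            0.204          0.0362
#> t = 2.379, d.f. = 89, two-tailed p = 0.01952
```

The first lines say that 64.0% of the global Seychelles Magpie-robin
population and 50.1% of the global African Penguin population are protected
through tourism revenue; the histogram shows most species cluster below 5%,
with nine at exactly zero (their reserves receive no tourism income); and the
comparison shows CR species rely significantly more heavily on tourism than
EN species on the transformed scale.

The same verbs run on your own data or on synthetic worlds:

```r
world <- read_world("species.csv", "subpopulations.csv",
                    "protected_areas.csv", "country_revenue.csv")
res   <- account_species(world)
coverage_funnel(world$species, world$subpopulations, res)

w <- generate_world(generator_config(seed = 42))   # synthetic, ground truth known
all(account_species(w)$T == w$ground_truth$species$true_T)
```

A thin command-line front end wraps the pipeline:

```sh
exec/tourishare compute --fixtures --out out/
exec/tourishare simulate --seed 1 --out world/
```

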