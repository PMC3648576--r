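---
title: "Tourism-revenue accounting for threatened species: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tourism-revenue accounting for threatened species: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tourishare)
```

## The accounting model

For each threatened species the package computes

$$T = \frac{\sum_{n} S_n R_n}{G},$$

the proportion of the species' global population $G$ whose protection is
funded by tourism: $S_n$ is the size of the subpopulation inside protected
area $n$ and $R_n$ is the proportion of that area's management budget derived
from tourism. The statistic assumes that conservation benefit scales with the
budget share, that funds within a national parks agency are fungible (agencies
routinely transfer money between areas, which is why $R$ is resolved at
national scale by default), and that the point estimate $G$ is an adequate
denominator — published range bounds are carried as data
(`pop_low`/`pop_high`) but never enter the calculation.

Three rules govern which records enter the sum:

* **Eligibility.** Non-migratory species contribute only `resident`
  subpopulations; migratory species contribute only records at significant
  breeding sites (`occupancy == "breeding"`). What counts as "significant" is
  a judgement delegated to the data compiler through the occupancy code: the
  package applies the code, it does not re-derive it.
* **Zero is data, missing is not.** An area whose country demonstrably earns
  no tourism revenue enters the sum with $R = 0$ and pulls $T$ down. An area
  whose revenue share is simply unknown is excluded from the numerator, and
  the species is downgraded to `coverage = "partial"` so downstream users
  know its $T$ is a lower bound over the known subpopulations. Species with
  no usable record at all get `coverage = "none"` and are excluded from all
  summaries and tests.
* **Consistency guard.** If the summed subpopulation sizes used for a species
  exceed its global population, the inputs are contradictory and the
  accounting stops with an error naming the species. Clamping would silently
  fabricate a valid-looking $T$.

Site-level overrides (`revenue_share_override`) take precedence over the
national share; their intended use is private reserves financed entirely by
tourism, where the national figure would be badly wrong.

## Reporting conventions and numerics

$T$ is kept at full floating precision internally and rendered as a
one-decimal percentage only at report time, rounding **half away from zero**.
The bundled 91-species reference table contains exact decimal halfway cases
(e.g. $100 \times 87/2000 = 4.35$, printed as 4.4), and IEEE doubles store
4.35 as 4.3499…96, so a naive `floor(x*10 + 0.5)` would round them down.
`round_half_up()` therefore adds a relative epsilon of $10^{-9}$ before
flooring: large enough to absorb binary representation error, far too small
to move any genuinely non-halfway value (the nearest non-halfway table value
sits $10^{-3}$ from a boundary). Under this convention all 91 published
percentages reproduce exactly from the printed $SR$ and $G$, which is the
package's core correctness check.

Histogram bins operate on the **rounded** percentage, not raw $T$, with
edges $\{0\}, (0,5), [5,10), [10,20), [20,100]$ and boundary values falling
rightward. This is the only convention under which the published bin counts
(9 / 41 / 21 / 8 / 12) are consistent with the species table: only six
species have $SR = 0$, but three more have tiny positive $SR$ that prints as
0.0%, and the published zero count of nine matches the rounded convention.
The discrepancy is documented here rather than resolved — the package follows
the printed table.

A related inconsistency in the source tables is carried as-is: the
compilation text reports 131 subpopulations for the 91 species while the
per-species count column sums to a different total, with a footnote that
further subpopulations without data may exist. The column is stored as data
(`n_subpops`) and never used to recompute $T$; only the printed aggregate
$SR$ is treated as a quantity.

## The inferential layer

`compare_groups()` tests whether mean $T$ differs between the CR and EN
threat classes, on the arcsine-square-root scale
($\arcsin\sqrt{T}$, the classical variance-stabilising transform for
proportions; $T$ enters as a proportion, since percentages would leave the
domain). The default is the **pooled-variance** two-sample t-test: on the
bundled table it gives $n_1 + n_2 - 2 = 89$ degrees of freedom, matching the
published d.f., which the Welch correction would not generally produce. The
Welch variant remains available (`variant = "unequal"`) as a sensitivity
check. On the bundled table the pooled test gives $t = 2.379$, $p = 0.0195$,
in the published direction (CR above EN) and below the published $p < 0.02$
threshold; the published $t = 0.082$ is inconsistent with that $p$ at
d.f. = 89 and is evidently a misprint, so the package's tests assert the
degrees of freedom and the direction, not the printed $t$.

`regress_T_on_G()` asks whether small populations rely more on tourism. The
source compilation does not state which transform of $T$ was fitted, so the
variant is explicit:

* `"arcsine"` (default): $\arcsin\sqrt{T}$ on $\ln G$. Chosen as the default
  because the published d.f. of 89 implies all 91 species — including the
  $T=0$ ones — were fitted, and the arcsine transform is the only one of the
  candidates defined at zero.
* `"loglog"`: $\ln T$ on $\ln G$ over the $T > 0$ subset, for sensitivity.
* `"log1p_percent"`: $\ln(T_\% + 1)$ on $\ln G$ using the rounded one-decimal
  percentages. Empirically this is the convention that reproduces the
  published fit statistics exactly ($R^2 = 0.008$, $p = 0.397$, d.f. = 89),
  so it is the best available reconstruction of how the published regression
  was computed; it is not the default because it depends on the rendered
  (rounded) values rather than the underlying proportions.

p-values come from `stats::t.test()` and `stats::lm()`; the test suite
checks them against hand-written pooled-t algebra, brute-force normal
equations, and numerical integration of the t density, keeping the
implementation and its oracles on separate routes.

## The synthetic-world generator

`generate_world()` builds all four input tables plus ground truth, so the
whole pipeline can be verified end-to-end without any external data. Its
defaults are fixed at the scale of the real compilation: 562 candidate
species with 190 CR; 43% of species with no protected-area record; 77
countries averaging ~6.75 protected areas each (≈520 areas); protected
species occurring in mostly 1–6 areas (1 + Poisson(0.45) draws); national
revenue shares Beta(1.5, 3.5) — bulk mass between roughly 5% and 80% — with
an 8% zero-revenue atom and 18% of countries missing from the revenue table
entirely (financial statements are rare); 20% migratory species; and each
protected species' total protected fraction of $G$ drawn uniformly from
[0.02, 0.6]. Where the real compilation pins no value (the Beta shapes, the
protected-fraction interval, the decoy and override rates) the defaults were
chosen once as field-plausible and are documented here, not tuned.

Construction guarantees the accounting preconditions: the total protected
count is drawn as a fraction of $G$ and then partitioned across
subpopulations by normalised Gamma weights with flooring, so
$\sum S_n \le G$ always holds (the error path is exercised separately with
deliberately corrupted tables). Occupancy codes are consistent with the
migratory flag for countable records, and a quarter of protected species
receive one decoy record with a non-countable occupancy to exercise the
eligibility filter. Private reserves carry a site override drawn from the
same zero-inflation regime as national shares, so a world configured with
universal zero revenue genuinely has $T = 0$ everywhere. A `status_effect`
parameter shifts CR species' protected fractions additively (clamped to
[0, 1]); zero gives an exchangeable null world for calibration.

What the generator does **not** emulate: real biogeography (island endemism,
range structure), correlations between threat status and population size,
country-level heterogeneity in data quality, and any dependence between a
species' presence and an area's revenue. Passing tests therefore demonstrate
that the pipeline computes its statistic correctly and that the test holds
its nominal level under the generator's null — not that the model's
assumptions hold in real data.

## Problem sizes and stochastic tolerances

The test suite and the acceptance script use fixed problem sizes chosen to
make stochastic checks sharp but cheap: exact ground-truth recovery over 20
worlds of 70 species; a type-I calibration of the pooled test over 2000 null
worlds of 80 species (asserted within ±0.02 of 0.05, about four binomial
standard errors at that replicate count, with slack for the t-test's
approximation on skewed transformed proportions — measured rates sit near
0.04–0.055); and a power smoke test at 200 species with a +0.4 status effect,
where rejection frequency exceeds 90%. Calibration replicates evaluate
`compare_groups()` on the generator's ground-truth $T$ table, which the
exact-recovery property shows is identical to the pipeline's output, keeping
the 2000-replicate loop inexpensive.

## Known limitations

* $T$ inherits every limitation of its inputs: population counts and revenue
  shares are point values with no uncertainty propagation; a species'
  `partial` coverage biases $T$ downward by an unknown amount.
* National-scale $R$ misstates areas whose budgets are not fungible with the
  national agency's; site overrides mitigate this only where known.
* The statistic is gross, not net: tourism's disturbance costs to the same
  species are outside the accounting.
* Range-based alternatives for species without subpopulation counts, and any
  ecological population modelling, are out of scope.
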