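# fvgap

Tools for quantifying the gap between fruit-and-vegetable (F&V) supply,
demand, and recommended consumption levels at country, regional and global
scale. The package is aimed at food-systems and nutritional-epidemiology
modellers who want a transparent, fully testable desk-scale version of the
partial-equilibrium projection workflow: simulate availability under
alternative socioeconomic futures, compare it against population-weighted
dietary targets, stress it with household-waste scenarios, and classify the
public-policy landscape on the Nuffield intervention ladder.

Because the real inputs (commodity balance sheets, UN population pyramids,
SSP projections, policy databases) are large external databases, `fvgap`
ships a seeded synthetic-world generator that reproduces their statistical
structure — age-structured demography hitting scenario anchors, trade-
consistent commodity balances, Engel-consistent elasticities — so the whole
pipeline runs end-to-end, deterministically, from a single seed.

## The model

Each commodity *i* trades on one integrated world market. Demand and supply
are constant-elasticity:

- food demand: `QD_food(c,i) = α(c,i) · N(c) · (y(c)/y0(c))^εy · P(i)^εp`
- other (processing/storage) demand: `QD_other = λ · QD_food`
- supply: `QS(c,i) = β(c,i) · P(i)^γ · Π_s (1 + g(c,i,s))`

with population `N`, per-capita income `y`, world price index `P` (base
year = 1), income elasticity `εy > 0`, own-price elasticity `εp < 0`,
supply elasticity `γ > 0` and exogenous annual supply growth `g`. For each
year the world price solves the market-clearing condition
`Σ_c [QD_food + QD_other] = Σ_c QS`; because `γ − εp > 0` the excess demand
is strictly monotone and the equilibrium unique. Parameters are calibrated
so the base year reproduces the panel's balances exactly.

Per-capita availability is `A(c) = Σ_i QD_food(c,i) · 10^6 / (365 · N(c))`
in g/person/day. Waste-adjusted consumption is `C = A·(1 − w)`; targets are
the flat 400 g/person/day minimum and the pyramid-weighted age-specific
level `R = Σ_a N_a r_a / Σ_a N_a` with `r = (330, 480, 600)` g/person/day
for ages 0–4, 5–14 and 15+.

## Worked example

```r
library(fvgap)

world <- generate_world(world_config(n_countries = 20, seed = 7))
sim   <- simulate_market(world, "SSP1")
sim
#> <fv_equilibrium> scenario SSP1, years 1961-2050, max |residual|/supply = 2.37e-13

targets <- target_series(world, "SSP1")
gap <- gap_table(sim$availability, targets,
                 waste_scheme("uniform", share = 0.15), world$countries)
glob <- summarize_gap(gap, world, "global")
subset(glob, year == 2050,
       c(availability, consumption, n_pass_min, population))
#>   availability consumption n_pass_min population
#>       602.8852    512.4524         16    8.5e+09
```

Availability is the population-weighted global mean in g/person/day before
household waste; `consumption` removes the 15% waste share; `n_pass_min`
counts countries whose waste-adjusted consumption meets the 400 g minimum.
Under the pessimistic scenario the same world yields a 2050 availability of
403 g — economic growth alone moves the global mean by roughly 50%.

The policy side:

```r
db  <- generate_policy_db(200, seed = 8, fv_fraction = 0.22)
fv  <- filter_fv_policies(db)                  # keyword rule: fruit|vegetable
lvl <- expand_regions(fv)                      # EU -> 28, CARICOM -> 15, ...
lvl$rung <- map_to_nuffield(lvl$category)
```

`run_pipeline(run_config(seed = 1), "out/")` chains every stage and writes
the declared CSVs plus a deterministic manifest; `validate_tables("out/")`
re-checks schemas and cross-table invariants.

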