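---
title: "Methods: a desk-scale partial-equilibrium model of fruit and vegetable gaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale partial-equilibrium model of fruit and vegetable gaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fvgap)
```

## What the package models

`fvgap` projects per-capita fruit-and-vegetable (F&V) availability for a
panel of countries under alternative socioeconomic scenarios and compares
it against recommended consumption levels. It is a deliberately *simplified*
multimarket model: full-scale agricultural sector models couple dozens of
commodities to biophysical crop and water modules across 150+ countries;
here, the economic core of that workflow — elasticity-driven demand,
price-responsive supply, trade linkage through integrated world markets,
annual recursive dynamics — is retained at a scale where every component
can be verified against closed forms and independent oracles.

## The market model

For commodity $i$ in country $c$ and year $t$:

$$QD^{food}_{c,i} = \alpha_{c,i}\, N_{c,t}\,
  \left(\frac{y_{c,t}}{y_{c,0}}\right)^{\varepsilon_y}
  P_i^{\varepsilon_p}, \qquad
QD^{other}_{c,i} = \lambda_{c,i}\, QD^{food}_{c,i},$$

$$QS_{c,i} = \beta_{c,i}\, P_i^{\gamma} \prod_{s > t_0} (1 + g_{c,i,s}).$$

The world price $P_i$ (an index, base year $=1$) clears the global market,
$\sum_c (QD^{food} + QD^{other}) = \sum_c QS$. Key modelling choices:

- **Constant elasticity.** No functional form is dictated by the data the
  model emulates; the log-linear form gives closed-form toy solutions
  (a demand shifter $k$ against supply clears at
  $P^\ast = k^{1/(\gamma - \varepsilon_p)}$), and with
  $\varepsilon_p < 0 < \gamma$ the world excess demand is strictly
  decreasing, so the equilibrium exists, is unique, and can be bracketed.
- **One integrated market per commodity.** No bilateral flows, no trade
  margins (price transmission = 1). Net trade is the residual
  $QS - QD^{food} - QD^{other}$ and sums to zero globally by construction.
- **Other demand as a calibrated share.** Processing and storage losses are
  an accounting category, not a behavioural agent, so they scale with food
  demand through $\lambda = QD^{other}_0 / QD^{food}_0$. Post-harvest
  losses are implicit in the calibrated supply intercept $\beta$.
- **Recursive annual dynamics.** Drivers update each year; there is no
  intertemporal optimisation. Years before the base year replay the panel's
  base balances (history is data, not model); the base year itself runs
  through the solver, which must — and does — recover all prices at 1 and
  the base balances exactly (the calibration identity, verified to 1e-9
  relative in the tests).

### Numerical choices

The solver is Brent-style bracketed root finding (`stats::uniroot`,
tolerance `1e-12` on the price) on an initial bracket $[0.25, 4]$ expanded
geometrically to hard bounds $[10^{-3}, 10^3]$; exceeding the bounds raises
a non-convergence error naming the commodity, year and boundary residuals.
An empty market (zero demand and supply) conventionally keeps the base
price. Cross-price effects are off by default, keeping commodities
separable; an optional cross-elasticity matrix switches to damped
fixed-point iteration on the price vector (damping 0.5, at most 500
iterations, relative tolerance `1e-8`), followed by one exact clearing pass
at the settled price vector. Tests confirm the fixed point reduces to the
separable solution at zero cross-elasticities.

## Recommendation targets

Two target sets are built in: the flat minimum of 400 g/person/day, and
age-specific levels of 330 (ages 0–4), 480 (5–14) and 600 (15+)
g/person/day weighted by each country-year's population pyramid,
$R = \sum_a N_a r_a / \sum_a N_a$. Weighting uses band populations
directly, so $R$ is scale-invariant, bounded by the extreme band levels,
and exactly equal to a per-individual average — the property the test
suite checks against a brute-force oracle. Only the three bands that enter
the weighting are modelled. Historical years use the panel's single
(scenario-independent) historical pyramid and are flagged in the output so
that scenario differences are attributable to demography alone.

## Waste scenarios and gap summaries

Household waste is the wedge between availability (what reaches the
household) and consumption: $C = A(1-w)$. Three scheme kinds cover the
analysis designs in use: `zero` (availability view), `uniform` (the
stylised 15% and 33% futures), and `regional` (an FAO-style table whose
only anchored entries are 5% for sub-Saharan Africa and 28% for North
America & Oceania; other regions default to an editable 15% placeholder).
Threshold comparisons are inclusive ($C \ge T$ passes). Because the
future country counts can be read either against availability or against
waste-adjusted consumption, the gap table emits both ratio columns
(`ratio_min`, `ratio_age`) and both pass flags rather than choosing one
reading. Group summaries are population-weighted means with passing-country
counts and passing populations; regions partition the world, so regional
rows sum to the global row exactly.

## Policy review

The policy module implements the review procedure: case-insensitive
keyword targeting on record descriptions ("fruit" or "vegetable";
substring by default so plurals match, word-boundary matching available),
expansion of regional-bloc records to every member country (EU = 28,
Caribbean Community = 15, Pacific Island Nations and Territories = 22),
mapping of taxonomy categories onto the seven-rung Nuffield intervention
ladder, and region × rung tabulation counting *distinct countries* with
zero rows retained for unobserved rungs. The category → rung table is
shipped as data (`extdata/nourishing_to_nuffield.csv`), not code; three
rows follow established precedent (store-owner location incentives →
enable choice, judged from the consumer's perspective; dietary guidelines
→ provide information; F&V price subsidies → guide choice with
incentives) and the remaining rows are synthetic implementation defaults
that users can edit.

## The synthetic world generator

The generator emulates the statistical structure of the real inputs, not
their values:

- **Population.** Country sizes are lognormal shares of a 6.9 billion
  base-year (2010) world. Future totals interpolate exponentially to
  country-level 2050 targets rescaled so each scenario hits its global
  anchor exactly (SSP1 8.5e9, SSP2 9.2e9, SSP3 9.95e9 persons).
  Child-band shares start at realistic levels (6–16% for ages 0–4, 12–26%
  for 5–14) and shrink linearly to 70% of their base value by 2050,
  giving every country an aging pyramid. Band populations always sum to
  totals because the adult band is the residual.
- **Income.** Lognormal heterogeneity around $9,000/person; log-linear
  paths to 2050 levels rescaled so the population-weighted global mean
  hits each scenario's GDP anchor ($34k / $25k / $18k). Because the same
  country-level heterogeneity is reused across scenarios, income paths are
  ordered SSP1 ≥ SSP2 ≥ SSP3 everywhere. Age-band shares are
  scenario-independent: the presets differ through totals and income only.
- **Balances.** Base per-capita demand is centred at 400 g/person/day and
  scales with income to the 0.35 power — an Engel-type cross-section.
  Production is demand times a lognormal factor; global trade closure is
  achieved by proportionally rescaling exporters' surpluses, the simplest
  closure that preserves non-negativity.
- **Elasticities.** Income elasticities decline with the country's income
  rank across [0.2, 1.0] (Engel-consistent); own-price in [−0.8, −0.2];
  supply in [0.2, 0.8]. These ranges are an explicit stand-in — the
  emulated modelling systems do not publish their values — chosen so that
  $\gamma - \varepsilon_p \ge 0.4$ everywhere, guaranteeing uniqueness.
- **Supply growth.** 0.5–2% per year per country-commodity, scaled by the
  scenario productivity multiplier (1.2 / 1.0 / 0.8), so optimistic
  futures pair faster technical change with higher incomes.

All draws flow from a single seed; generation is deterministic and CSV
output byte-identical per (config, seed).

**What passing tests do and do not show.** The generator produces smooth,
noise-free trajectories, a single representative consumer per country, no
intra-country distribution, no climate or extreme-event shocks, and
commodity aggregates rather than individual crops. Tests passing on this
world demonstrate that the *machinery* — calibration, clearing, weighting,
waste arithmetic, classification — is correct, not that any particular
real-world projection is right; magnitudes depend on the synthetic
conditions.

## Problem sizes and defaults

The default world is 20 countries, 7 regions, 4 commodities
(three fruit aggregates, one vegetable aggregate), 1961–2050 with base
year 2010 and three scenario presets — large enough to exercise regional
aggregation and trade heterogeneity while keeping a full three-scenario
simulation under a second. The pipeline's default waste set is
{zero, regional, 15%, 33%}; snapshot reporting years are 1965, 1990,
2015, 2030, 2050.

## Known limitations

- Elasticities are constant per country-commodity over time; systems that
  re-estimate them along the income path will diverge from this model in
  long projections.
- Historical years replay the base-year balances, so historical
  availability varies only through population; users with real historical
  balance panels should inject them rather than rely on the replay.
- The single-world-market assumption removes all price wedges between
  countries; availability responses to scenario shocks are therefore more
  synchronised than in models with bilateral trade costs.
- The policy taxonomy beyond its three anchored rows is a synthetic
  default, intended to be replaced by a user-maintained mapping file.
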