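---
title: "A fiscal burden-of-disease model for overweight and obesity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A fiscal burden-of-disease model for overweight and obesity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiscalbod)
```

## The model

`fiscalbod` estimates the burden that overweight and obesity (OAO) place
on government accounts: tax revenue forgone plus transfer and healthcare
spending incurred, from a government-accounts perspective. It is a
prevalence-based counterfactual comparison, not a comorbidity
cost-of-illness model: instead of attributing the costs of individual
obesity-related diseases, it compares the fiscal flows of the observed
population (the *control* cohort) with a hypothetical *intervention*
cohort in which everyone in the OAO categories is reassigned to normal
weight.

The population is stratified by age band and sex. Within each stratum
$(i, j)$ the population is split over four BMI categories $k$
(underweight $<18.5$, normal $18.5$–$<25$, overweight $25$–$<30$, obese
$\ge 30$); OAO is the union of the overweight and obese categories
(BMI $\ge 25$, the categorisation commonly used for Japanese and other
Asian populations, in whom weight-related health effects appear at lower
BMI), with the WHO cut-off (BMI $\ge 30$) available as a scenario.

For each stratum and BMI group the model applies, in order:

1. **Employment** ($P(E)$): the general-population probabilities of
   full- and part-time employment are shifted additively for the OAO
   group by the regression marginal effect $\beta_E$, clamped to
   $[0,1]$. The retired are removed from the employment-eligible pool
   first, so nobody is simultaneously retired and employed.
2. **Welfare rates**: sick-leave and (early-)retirement rates are
   multiplied by published hazard ratios for the OAO group.
3. **Income** ($Y$): labor income is shifted relatively,
   $Y_{OAO} = Y_{GP}(1 + \beta_Y)$.
4. **Income aggregation**: total stratum income combines full-time
   workers not on sick leave, part-time workers, and full-time workers
   on sick leave, who receive a fraction of salary (default $2/3$, the
   Japanese sickness-allowance replacement rate). A scenario switch
   extends the sick-leave split to part-time workers.
5. **Direct tax**: the tax wedge $w$ (total labor taxes including
   employer contributions over labor cost) applied to total income.
6. **Indirect tax**: VAT applied to disposable income $(1-w)Y$ *and* to
   transfer income — pension payments are partly consumed, so removing
   OAO also removes a small amount of consumption-tax revenue.
7. **Healthcare** ($HC$): mean medical expenditure per capita ($MEPC$)
   is redistributed with the OAO-attributable fraction $AF$: non-OAO
   categories carry $(1-AF)\,MEPC$ and OAO categories carry
   $(1-AF)\,MEPC + AF \cdot MEPC / p$, where $p$ is the stratum's OAO
   prevalence. The prevalence-weighted mean is conserved exactly in the
   control cohort.
8. **Mortality**: OAO-attributable deaths follow the Rockhill
   population-attributable fraction
   $PAF = \sum_k pd_k\,(RR_k - 1)/RR_k$, with the case (death)
   distribution $pd_k \propto X_k RR_k$ derived from prevalence and the
   category relative risks, applied to band-averaged life-table death
   probabilities.

The net fiscal effect of a cohort is
$\text{net} = \text{direct tax} + \text{indirect tax} -
\text{pensions} - \text{healthcare}$, and the burden of OAO is the
difference between the intervention and control cohorts, decomposed
into direct tax losses, indirect tax losses, excess retirement payments
and excess healthcare costs. All four components are positive when OAO
is harmful, and they sum to the total by construction.

```{r base-case}
inp <- japan_like_fixture()
fit <- fiscal_bod(inp$strata, inp$modifiers, inp$fiscal)
fit
```

## Parameters and defaults

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `tax_wedge` | labor taxes / labor cost | 0.327 | OECD-style Japanese wedge |
| `vat_rate` | consumption tax | 0.10 | Japanese VAT |
| `sickpay_fraction` | salary replaced on sick leave | 2/3 | Japanese sickness allowance |
| `pension_benefit` | JPY/retiree/year | 1.8e6 | order of the average employee pension |
| `discount_rate` | per year | 0.02 | Japanese HTA guidance |
| `wage_growth` | per year | 0.02 | average year-on-year cash-earnings growth |
| `prevalence_growth` | OAO share growth per year | 0.0147 (M) / 0.0047 (F) | forecasting-study averages |
| `age_range` | base-case population | 18–70 | working-age focus |

Modifier scales: $\beta_E$ is additive on the probability scale (it is
a marginal effect from an employment regression), $\beta_Y$
multiplicative (a relative wage effect), hazard ratios multiply rates,
and mortality relative risks are per BMI category with normal weight as
the reference. Each labor modifier may be pooled or sex-specific; a
pooled value is used for both sexes when no sex-specific one is given.

## Counterfactuals, projection and the reduction curve

`build_intervention_cohort()` moves all OAO mass to the normal-weight
category, conserving stratum counts exactly. `reduction_curve()`
evaluates partial counterfactuals: a fraction $f$ of each OAO
category's mass is reassigned, so $f=0$ reproduces the control cohort
(zero gain) and $f=1$ the full burden.

`project_burden()` grows each stratum's combined OAO share
multiplicatively at the sex-specific rate (preserving the internal
overweight:obese ratio, drawing mass from normal weight and clamping —
with a warning — when normal weight would go negative), grows wages by
2% per year, and discounts at 2%. Because wage growth and discounting
cancel at the default rates, the growth of the discounted series over
the horizon (`decade_growth()`) isolates the prevalence effect. Two
deliberate structural choices:

* The per-category healthcare price tags are anchored to the base-year
  control prevalence, so the per-OAO-person mark-up
  $AF \cdot MEPC / p_0$ is the structural constant and excess
  healthcare spending grows with OAO prevalence. Re-deriving the
  mark-up each year from the grown prevalence would instead hold the
  aggregate attributable spend fixed, which contradicts the premise
  that a growing exposed population costs more.
* Per-capita medical expenditure grows with wages by default
  (`grow_mepc = TRUE`), pension benefits are held fixed in real terms,
  and population counts are held constant unless a projection table is
  supplied (a notice is logged).

Deaths attributable to OAO reduce the OAO group's labor income and
transfer receipts by half a person-year each (mid-year convention) in
the year they occur. This is the most conservative symmetric treatment
of within-year mortality and can be disabled with
`mortality_adjust = FALSE`.

## The lifetime cohort model

`lifetime_fiscal_effect()` follows one OAO individual and one non-OAO
peer from a starting age to the life table's terminal age; neither can
switch status. Both arms face the same baseline early-retirement hazard
from age 50 (the OAO arm's hazard scaled by the retirement hazard
ratio) and full statutory retirement at 65. Applying the baseline
hazard to both arms — rather than only the OAO arm — keeps the
comparison like-for-like: with all modifiers null the two arms are
identical and the lifetime burden is exactly zero, which is the
property a counterfactual comparison must have.

Arm-specific mortality splits the life table's population-average
$q_x$ using the prevalence-weighted OAO relative risk $\bar{RR}$:
$q_x^{non} = q_x / (1 - p + p\bar{RR})$ and
$q_x^{OAO} = \bar{RR}\, q_x^{non}$, so the population mix reproduces
the life table. Beyond the oldest stratum band, medical expenditure and
welfare rates carry the last band's values forward; employment income
is already extinguished by statutory retirement. Flows are weighted by
start-of-year survival and discounted; the per-person burden is
$PV(\text{non-OAO}) - PV(\text{OAO})$, reported as a tax-loss and a
transfer component that sum to the total. In an age sweep the tax-loss
component shrinks with starting age (fewer working years remain) while
the transfer share grows.

## Sensitivity and scenarios

`run_owsa()` varies one parameter at a time between a low and a high
value (default $\pm 20\%$ of base when no confidence interval is
available) and reports burden totals sorted by bar width. Note the
usual caveat for ratios near 1: a relative range on a hazard ratio of
1.16 swings the *excess* (HR $-$ 1) by far more than $\pm 20\%$, which
inflates its bar relative to parameters whose base value is far from
the null.

`run_scenarios()` reruns the model end-to-end under overrides: age
ranges 18–65 / 18–75 / 18–104, the WHO obesity definition, alternate
mortality relative risks at ages $\ge 65$, sick leave for part-timers,
and single-sex populations (the excluded sex's counts are zeroed so
output shapes stay constant). Every row satisfies
net = tax loss + transfer spending.

## Synthetic data: what it emulates and what it does not

The study-grade inputs (national survey BMI prevalence, labor
statistics, expenditure tables, official life tables) are not
redistributable, so the package generates its own:

* `generate_parameter_set()` draws seeded random input sets with the
  documented shapes — OAO prevalence rising logistically with age to a
  sex-specific plateau near 60, hump-shaped employment and income
  profiles (log-normal noise around the band means), exponentially
  rising medical expenditure, and a Gompertz life table
  ($q_x \propto e^{0.095\,\text{age}}$, capped at 1, terminal age 105).
* `japan_like_fixture()` is the same machinery with the noise removed
  and magnitudes set once to Japan-2023-like values: about 75 million
  people aged 18–70, overall OAO prevalence near 25% (higher in men),
  full-time income peaking near ¥4.5 million, and the published fiscal
  constants (tax wedge 0.327, VAT 10%, discount and wage growth 2%,
  prevalence growth 1.47%/0.47%). The modifier values (employment
  effect $-0.035$, income effect $-0.05$, sick-leave HR 1.27,
  retirement HR 1.16, mortality RR 1.07/1.36 for
  overweight/obese, healthcare attributable fraction 0.035) are
  literature-plausible synthetic choices consistent with the
  qualitative sensitivity structure reported for Japan (employment
  modifiers and the tax wedge dominate); they are **not** the study's
  inputs, and the fixture's headline outputs are right in order of
  magnitude only. The published 2023 decomposition
  (¥901.23 / ¥178.65 / ¥76.80 / ¥768.58 billion, total ¥1925.26
  billion) is therefore exercised through the reporting layer's
  arithmetic identities, not re-derived from the fixture.

Passing tests on these inputs demonstrate the engine's identities,
invariances and orderings (zero burden under null modifiers, mass and
expenditure conservation, endpoint and decomposition identities,
direction of age and definition effects). They do not validate the
magnitude of any real-world estimate, which is entirely input-driven.

The interchange formats are deliberately plain: a CSV stratum table
(one row per age band and sex), a CSV life table (`sex, age, qx`), and
a flat `[fiscal]/[modifiers]/[run]` key-value configuration file with
documented defaults for omitted keys.

## Numerical choices and degenerate inputs

* Probabilities are clamped to $[0,1]$ after modifier application;
  incomes are floored at 0.
* The attributable-fraction redistribution is a domain error when
  $AF > 0$ with no exposed population in the reference prevalence
  (there is nothing to attribute); the engine treats a cohort whose
  *reference* prevalence has no OAO as carrying unadjusted expenditure.
* Band-level $q_x$ is the unweighted mean of single-year $q_x$ over the
  band.
* $PAF$ terms with $pd_k = 0$ contribute 0 even when $RR_k$ would be
  degenerate; $RR_k = 0$ with $pd_k > 0$ is a domain error.
* Zero-population strata and zero-width sensitivity ranges are valid
  and produce zero flows / zero-width bars.
* Validation is report-based (every breach with row and field
  coordinates) rather than fail-fast, so a malformed table can be
  diagnosed in one pass; constructors and readers stop on a non-empty
  report.

## Problem sizes

The shipped analyses are small by construction: 18 age bands × 2 sexes
(36 strata, 22 in the 18–70 base case), an 11-year projection, and
lifetime paths of at most ~60 ages × 2 arms × 2 sexes. A full base-case
fit takes well under a second; the property suites (100 seeded
populations for the null-modifier identity) run in seconds.

## Known limitations

* Single tax wedge — no progressive schedule; no presenteeism costing.
* No BMI-category transitions within a year (static prevalence model);
  the lifetime model fixes status for life.
* The same employment effect is applied to full- and part-time work.
* Population counts are flat over the projection horizon unless a
  projection table is supplied.
* The universal old-age pension common to both cohorts cancels in the
  burden; the `retirement` column should therefore carry the
  OAO-modifiable (early) retirement margin.
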