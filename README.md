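# fiscalbod

A government-perspective (fiscal) burden-of-disease model for overweight
and obesity (OAO, BMI ≥ 25 kg/m²).

Health economists usually cost obesity through its comorbidities.
`fiscalbod` takes the public-accounts view instead: how much tax revenue
does a government forgo, and how much extra transfer and healthcare
spending does it incur, because part of its population is overweight or
obese? The model stratifies a population by age band, sex and four BMI
categories, applies published OAO effect sizes to labor-market and
health outcomes, and compares the fiscal flows of the observed
population (*control* cohort) with a counterfactual *intervention*
cohort in which all OAO mass is reassigned to normal weight.

For each stratum and BMI group:

- employment probabilities are shifted additively by the OAO marginal
  effect β_E (retired persons are removed from the eligible pool
  first); sick-leave and early-retirement rates are scaled by hazard
  ratios; income is shifted relatively by β_Y;
- total income combines full-time workers (net of sick leave),
  part-time workers and sick-leave recipients at a replacement fraction
  (default 2/3);
- direct tax = tax wedge × total income; indirect tax = VAT ×
  (disposable income + transfer income);
- per-capita medical expenditure is redistributed by the
  OAO-attributable fraction AF: non-OAO categories carry (1−AF)·MEPC,
  OAO categories carry (1−AF)·MEPC + AF·MEPC/p;
- OAO-attributable deaths follow the Rockhill population-attributable
  fraction PAF = Σₖ pdₖ (RRₖ−1)/RRₖ combined with life tables, and
  remove half a person-year of income and transfers each (mid-year
  convention).

The burden is the control-vs-intervention difference in
net = direct tax + indirect tax − pensions − healthcare, decomposed
into direct tax losses, indirect tax losses, excess retirement payments
and excess healthcare costs. On top of the annual model the package
provides a multi-year projection (prevalence growth by sex, wage
growth, discounting), a prevalence-reduction curve, a per-person
lifetime cohort model, one-way sensitivity analysis (tornado) and a
scenario battery, plus a synthetic-data generator so that everything is
testable without restricted national statistics.

## Worked example

```r
library(fiscalbod)

inp <- japan_like_fixture()   # fixed synthetic Japan-2023-like inputs
fit <- fiscal_bod(inp$strata, inp$modifiers, inp$fiscal)
fit
#> Fiscal burden-of-disease model (OAO)
#>   OAO definition: overweight + obese
#>   Age range: 18-70, sex: both
#>   Population: 70.0 million
#>                                              component billion_jpy billion_usd
#>                      Direct tax losses from employment     1315.29        9.16
#>  Indirect tax losses (employment income and transfers)      254.41        1.77
#>                                    Retirement payments      162.89        1.13
#>                                       Healthcare costs      758.21        5.28
#>                             Total fiscal burden of OAO     2490.80       17.35
```

Read the table as: with this input set, OAO costs the government about
¥2.5 trillion per year, mostly as direct tax revenue lost to lower
employment and income (¥1315 bn) and attributable healthcare spending
(¥758 bn); the four components sum to the total by construction. The
fixture's modifiers are synthetic, literature-plausible values — the
magnitudes are of the right order for Japan but are not a reproduction
of any published estimate.

```r
lifetime_fiscal_effect(49, inp$modifiers, inp$fiscal,
                       inp$life_table, inp$strata)
#> Per-person lifetime fiscal burden of OAO (start age 49)
#>   Tax revenue loss:       1736630 JPY
#>   Transfer spending:       842727 JPY
#>   Total:                  2579357 JPY
```

A 49-year-old with OAO costs the government about ¥2.6 million more
over the remaining lifetime than a non-OAO peer, two-thirds of it as
forgone tax. Other entry points: `project_burden()` /
`decade_growth()`, `reduction_curve()`, `run_owsa()`,
`run_scenarios()`, and the CLI (`inst/exec/fiscalbod` with subcommands
`synth`, `run`, `project`, `lifetime`, `owsa`, `scenarios`, `curve`).
The methods vignette (`vignettes/fiscal-burden-model.Rmd`) documents
the model, its assumptions and design choices in full.

## File formats

- stratum table CSV: `age_lo, age_hi, sex, count, p_under, p_normal,
  p_over, p_obese, emp_ft, emp_pt, income_ft, income_pt, sickleave,
  retirement, mepc, mortality`
- life table CSV: `sex, age, qx` (single-year ages, terminal qx = 1)
- config: flat `key = value` file with `[fiscal]`, `[modifiers]`,
  `[run]` sections (see `load_config()` for keys and defaults)
- CLI outputs: `burden.csv`, `projection.csv`, `lifetime.csv`,
  `tornado.csv`, `scenarios.csv`, `curve.csv`, `run.log`
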