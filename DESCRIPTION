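Package: fiscalbod
Title: Fiscal Burden-of-Disease Modelling for Overweight and Obesity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A government-perspective (fiscal) burden-of-disease model for
    overweight and obesity (OAO). Tracks a population across BMI categories,
    applies labor-market and health modifiers (employment and income marginal
    effects, sick-leave and early-retirement hazard ratios, mortality relative
    risks, a healthcare attributable fraction), and compares tax revenue
    (direct via a tax wedge, indirect via VAT) and transfer spending (pensions,
    healthcare) between the observed population and a counterfactual cohort
    with OAO reassigned to normal weight. Includes multi-year projections with
    prevalence and wage growth under discounting, a per-person lifetime cohort
    model, prevalence-reduction curves, one-way sensitivity analysis and a
    scenario battery, plus a synthetic-data generator producing complete
    Japan-like input sets for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
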