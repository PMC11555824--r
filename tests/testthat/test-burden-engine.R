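# Counterfactual cohort construction, the annual flow engine, the burden
# decomposition, the reduction curve and the projection.

test_that("intervention cohort reassigns OAO mass to normal weight", {
  s <- toy_strata()
  int <- build_intervention_cohort(build_cohort(s))
  expect_equal(int$strata$p_normal, c(0.90, 0.88))
  expect_equal(int$strata$p_over, c(0, 0))
  expect_equal(int$strata$p_obese, c(0, 0))
  expect_equal(int$strata$p_under, s$p_under)
  # mass conservation
  expect_equal(int$strata$count, s$count)
  expect_equal(int$strata$p_under + int$strata$p_normal +
                 int$strata$p_over + int$strata$p_obese, c(1, 1))
  # nothing to remove leaves the cohort unchanged
  s0 <- s; s0$p_normal <- s0$p_normal + s0$p_over + s0$p_obese
  s0$p_over <- 0; s0$p_obese <- 0
  int0 <- build_intervention_cohort(build_cohort(s0))
  expect_equal(int0$strata$p_normal, s0$p_normal)
  # WHO definition removes only the obese category
  intw <- build_intervention_cohort(build_cohort(s), oao_set = "obese")
  expect_equal(intw$strata$p_over, s$p_over)
  expect_equal(intw$strata$p_obese, c(0, 0))
  expect_equal(intw$strata$p_normal, s$p_normal + s$p_obese)
})

test_that("annual flows match the hand-written two-stratum ledger", {
  s <- toy_strata(); mod <- toy_modifiers(); fis <- toy_fiscal()
  ctl <- annual_fiscal_effect(build_cohort(s), mod, fis)
  led <- ledger_flows(s, mod, fis, "control")
  expect_equal(ctl$direct_tax, led[["direct"]], tolerance = 1e-9)
  expect_equal(ctl$indirect_tax, led[["indirect"]], tolerance = 1e-9)
  expect_equal(ctl$transfers, led[["transfers"]], tolerance = 1e-9)
  expect_equal(ctl$healthcare, led[["healthcare"]], tolerance = 1e-9)
  expect_equal(ctl$net, led[["direct"]] + led[["indirect"]] -
                 led[["transfers"]] - led[["healthcare"]], tolerance = 1e-9)

  int <- annual_fiscal_effect(build_intervention_cohort(build_cohort(s)),
                              mod, fis)
  ledi <- ledger_flows(s, mod, fis, "intervention")
  expect_equal(int$direct_tax, ledi[["direct"]], tolerance = 1e-9)
  expect_equal(int$healthcare, ledi[["healthcare"]], tolerance = 1e-9)

  b <- fiscal_burden(ctl, int)
  expect_equal(b$total, sum(b$components), tolerance = 1e-12)
  expect_equal(unname(b$components["direct_tax_loss"]),
               ledi[["direct"]] - led[["direct"]], tolerance = 1e-9)
  expect_equal(unname(b$components["healthcare_excess"]),
               led[["healthcare"]] - ledi[["healthcare"]], tolerance = 1e-9)
})

test_that("null modifiers give identical cohort flows and zero burden", {
  s <- toy_strata(); fis <- toy_fiscal()
  fit <- fiscal_bod(s, null_modifiers(), fis, age_range = NULL)
  expect_equal(fit$burden$total, 0, tolerance = 1e-6)
  expect_equal(unname(fit$burden$components), rep(0, 4), tolerance = 1e-6)
  expect_equal(fit$control_flows$net, fit$intervention_flows$net,
               tolerance = 1e-12)
})

test_that("zero population produces zero flows", {
  s <- toy_strata(); s$count <- 0
  fl <- annual_fiscal_effect(build_cohort(s), toy_modifiers(), toy_fiscal())
  expect_equal(fl$net, 0)
  expect_equal(fl$direct_tax + fl$indirect_tax + fl$transfers +
                 fl$healthcare, 0)
})

test_that("flows identity net = taxes - spending holds per stratum", {
  inp <- japan_like_fixture()
  fl <- annual_fiscal_effect(build_cohort(inp$strata), inp$modifiers,
                             inp$fiscal)
  by <- attr(fl, "by_stratum")
  expect_equal(by$net,
               by$direct_tax + by$indirect_tax - by$transfers - by$healthcare,
               tolerance = 1e-9)
})

test_that("reduction curve is zero at f=0, the burden at f=1, and
           monotone for harmful modifiers", {
  s <- toy_strata()
  fit <- fiscal_bod(s, toy_modifiers(), toy_fiscal(), age_range = NULL)
  cv <- reduction_curve(fit, fractions = seq(0, 1, by = 0.1))
  expect_equal(cv$gain[1], 0)
  expect_equal(cv$gain[nrow(cv)], fit$burden$total, tolerance = 1e-9)
  expect_true(all(diff(cv$gain) > 0))
  expect_error(reduction_curve(fit, fractions = c(0.5, 0.1)), "sorted")
})

test_that("single-step projection matches the closed form", {
  # no prevalence growth, no pension: every flow scales with wages, so
  # year 1 equals the base burden times the wage factor; discounting
  # applies on top
  s <- toy_strata()
  fis <- fiscal_params(tax_wedge = 0.327, vat_rate = 0.1,
                       pension_benefit = 0, discount_rate = 0.03,
                       wage_growth = 0.02,
                       prevalence_growth = c(male = 0, female = 0))
  fit <- fiscal_bod(s, toy_modifiers(), fis, age_range = NULL,
                    mortality_adjust = FALSE)
  proj <- suppressMessages(project_burden(fit, horizon = 1))
  expect_equal(proj$per_year$total[2], fit$burden$total * 1.02,
               tolerance = 1e-9)
  expect_equal(proj$per_year$discounted_total[2],
               fit$burden$total * 1.02 / 1.03, tolerance = 1e-9)
  expect_equal(proj$per_year$total[1], fit$burden$total, tolerance = 1e-12)
})

test_that("zero discount makes NPV the plain sum; growth raises the
           discounted series when wage growth offsets discounting", {
  s <- toy_strata()
  fis0 <- fiscal_params(discount_rate = 0, pension_benefit = 0,
                        prevalence_growth = c(male = 0.0147,
                                              female = 0.0047))
  fit0 <- fiscal_bod(s, toy_modifiers(), fis0, age_range = NULL)
  proj0 <- suppressMessages(project_burden(fit0, horizon = 5))
  expect_equal(proj0$npv_total, sum(proj0$per_year$total), tolerance = 1e-12)

  fis <- fiscal_params(discount_rate = 0.02, wage_growth = 0.02,
                       pension_benefit = 0)
  fit <- fiscal_bod(s, toy_modifiers(), fis, age_range = NULL)
  proj <- suppressMessages(project_burden(fit, horizon = 5))
  expect_true(all(diff(proj$per_year$discounted_total) > 0))
})

test_that("projection clamps OAO prevalence at the available normal mass", {
  s <- toy_strata()
  s$p_normal <- c(0.02, 0.02)
  s$p_over <- c(0.83, 0.80)
  s$p_obese <- c(0.05, 0.06)
  fis <- fiscal_params(prevalence_growth = c(male = 0.5, female = 0.5))
  fit <- fiscal_bod(s, toy_modifiers(), fis, age_range = NULL)
  w <- capture_warnings(proj <- suppressMessages(project_burden(fit,
                                                                horizon = 3)))
  expect_match(w, "clamped", all = TRUE)
  expect_true(all(is.finite(proj$per_year$total)))
})

test_that("projected population counts are taken from a projection table", {
  s <- toy_strata()
  pop <- data.frame(year = 2024, sex = "male", age_lo = 40, age_hi = 44,
                    count = 2000)
  fit <- fiscal_bod(s, toy_modifiers(), toy_fiscal(), age_range = NULL)
  proj <- project_burden(fit, horizon = 1, population = pop)
  # doubling the male stratum raises the year-1 burden well above base
  expect_gt(proj$per_year$total[2], 1.4 * proj$per_year$total[1])
})
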