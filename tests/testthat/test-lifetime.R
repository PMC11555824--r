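# Per-person lifetime cohort model.

lifetime_toy <- function() {
  # one band covering the whole test age range, female
  s <- data.frame(
    age_lo = 18, age_hi = 65, sex = "female", count = 1000,
    p_under = 0.1, p_normal = 0.6, p_over = 0.2, p_obese = 0.1,
    emp_ft = 0.6, emp_pt = 0.2, income_ft = 3e6, income_pt = 1e6,
    sickleave = 0.04, retirement = 0.05, mepc = 2.5e5, mortality = 0.01,
    stringsAsFactors = FALSE)
  lt <- data.frame(sex = "female", age = 63:65, qx = c(0.01, 0.02, 1))
  list(strata = s, life_table = lt)
}

test_that("three-age lifetime run matches the hand-discounted ledger", {
  toy <- lifetime_toy()
  mod <- toy_modifiers(); fis <- toy_fiscal()
  got <- lifetime_fiscal_effect(63, mod, fis, toy$life_table, toy$strata,
                                sex_mix = c(male = 0, female = 1))
  want <- ledger_lifetime(toy$strata, mod, fis, c(0.01, 0.02, 1),
                          p_oao = 0.3)
  expect_equal(got$total, want$total, tolerance = 1e-9)
  expect_equal(got$tax_loss, want$tax_loss, tolerance = 1e-9)
  expect_equal(got$transfer_excess, want$transfer_excess, tolerance = 1e-9)
  expect_equal(got$total, got$tax_loss + got$transfer_excess,
               tolerance = 1e-12)
  expect_equal(unname(got$pv["non_oao"] - got$pv["oao"]), got$total,
               tolerance = 1e-9)
})

test_that("null modifiers give zero lifetime burden; terminal start is a
           single-year difference", {
  toy <- lifetime_toy()
  fis <- toy_fiscal()
  got <- lifetime_fiscal_effect(63, null_modifiers(), fis, toy$life_table,
                                toy$strata, sex_mix = c(male = 0, female = 1))
  expect_equal(got$total, 0, tolerance = 1e-9)

  one <- lifetime_fiscal_effect(65, toy_modifiers(), fis, toy$life_table,
                                toy$strata, sex_mix = c(male = 0, female = 1))
  expect_equal(nrow(one$detail), 1)
  # at the terminal age both arms are retired; only healthcare differs
  expect_equal(one$tax_loss, 0, tolerance = 1e-9)
  expect_gt(one$transfer_excess, 0)

  expect_error(lifetime_fiscal_effect(80, toy_modifiers(), fis,
                                      toy$life_table, toy$strata,
                                      sex_mix = c(male = 0, female = 1)),
               "life table")
})

test_that("OAO-arm survival never exceeds the peer's when rr >= 1", {
  inp <- japan_like_fixture()
  r <- lifetime_fiscal_effect(49, inp$modifiers, inp$fiscal, inp$life_table,
                              inp$strata)
  expect_true(all(r$detail$surv_oao <= r$detail$surv_non + 1e-12))
  expect_equal(r$detail$surv_non[r$detail$age == 49], c(1, 1))
})

test_that("undiscounted present value is the plain survival-weighted sum", {
  toy <- lifetime_toy()
  fis <- fiscal_params(discount_rate = 0, wage_growth = 0,
                       pension_benefit = 2e6)
  got <- lifetime_fiscal_effect(63, toy_modifiers(), fis, toy$life_table,
                                toy$strata, sex_mix = c(male = 0, female = 1))
  d <- got$detail
  expect_equal(unname(got$pv["non_oao"]),
               sum(d$surv_non * (d$tax_non - d$spend_non)), tolerance = 1e-9)
  expect_equal(unname(got$pv["oao"]),
               sum(d$surv_oao * (d$tax_oao - d$spend_oao)), tolerance = 1e-9)
})

test_that("age sweep reduces to direct calls and shows the tax/transfer
           shift with starting age", {
  inp <- japan_like_fixture()
  one <- lifetime_age_sweep(49, sex = "both", modifiers = inp$modifiers,
                            fiscal = inp$fiscal,
                            life_table = inp$life_table,
                            strata = inp$strata)
  direct <- lifetime_fiscal_effect(49, inp$modifiers, inp$fiscal,
                                   inp$life_table, inp$strata)
  expect_equal(one$total, direct$total, tolerance = 1e-12)

  sweep <- lifetime_age_sweep(c(35, 49, 65), sex = "both",
                              modifiers = inp$modifiers, fiscal = inp$fiscal,
                              life_table = inp$life_table,
                              strata = inp$strata)
  # more working years remain at 35: the tax-loss component dominates
  # early and shrinks with age, while the transfer share grows
  expect_gt(sweep$tax_loss[1], sweep$tax_loss[3])
  expect_gt(sweep$transfer_excess[3] / sweep$total[3],
            sweep$transfer_excess[1] / sweep$total[1])

  null_sweep <- lifetime_age_sweep(c(40, 60), sex = "male",
                                   modifiers = null_modifiers(),
                                   fiscal = inp$fiscal,
                                   life_table = inp$life_table,
                                   strata = inp$strata)
  expect_equal(null_sweep$total, c(0, 0), tolerance = 1e-9)
})

test_that("single-sex lifetime runs differ and bracket the mixed run", {
  inp <- japan_like_fixture()
  args <- list(modifiers = inp$modifiers, fiscal = inp$fiscal,
               life_table = inp$life_table, strata = inp$strata)
  m <- do.call(lifetime_age_sweep, c(list(49, sex = "male"), args))
  f <- do.call(lifetime_age_sweep, c(list(49, sex = "female"), args))
  b <- do.call(lifetime_age_sweep, c(list(49, sex = "both"), args))
  expect_false(isTRUE(all.equal(m$total, f$total)))
  expect_equal(b$total, (m$total + f$total) / 2, tolerance = 1e-9)
})
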