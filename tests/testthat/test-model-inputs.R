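# Input containers, file round-trips, config parsing and validation.

test_that("BMI categories partition [0, Inf) with the standard cut-points", {
  cat <- bmi_categories()
  expect_identical(cat$label, c("underweight", "normal", "overweight", "obese"))
  expect_equal(cat$lower[-1], cat$upper[-nrow(cat)])  # no gaps/overlaps
  expect_equal(cat$lower[1], 0)
  expect_equal(cat$upper[nrow(cat)], Inf)
  expect_equal(cat$lower[2:4], c(18.5, 25, 30))
  expect_identical(oao_categories(), c("overweight", "obese"))
  expect_identical(oao_categories("who"), "obese")
})

test_that("stratum tables survive a write/read round-trip", {
  s <- toy_strata()
  path <- withr::local_tempfile(fileext = ".csv")
  write_stratum_table(s, path)
  s2 <- read_stratum_table(path)
  expect_equal(nrow(s2), 2)
  expect_equal(s2$p_over, s$p_over)
  for (col in setdiff(names(s), "sex"))
    expect_equal(s2[[col]], s[[col]], tolerance = 1e-9)
  expect_identical(s2$sex, s$sex)
})

test_that("schema and simplex violations are reported by name", {
  s <- toy_strata()
  path <- withr::local_tempfile(fileext = ".csv")
  write_stratum_table(s, path)
  d <- utils::read.csv(path)
  d$mepc <- NULL
  utils::write.csv(d, path, row.names = FALSE)
  expect_error(read_stratum_table(path), "mepc")

  bad <- toy_strata()
  bad$p_normal[1] <- 0.6  # proportions now sum to 0.9
  write_stratum_table(bad, path)
  expect_error(read_stratum_table(path), "sum")
})

test_that("validate_inputs reports every breach with coordinates", {
  inp <- japan_like_fixture()
  expect_equal(nrow(validate_inputs(inp$strata, inp$modifiers, inp$fiscal,
                                    inp$life_table)), 0)

  m <- inp$modifiers
  m$rr_mortality[["normal"]] <- 1.2
  rep <- validate_modifiers(m)
  expect_equal(nrow(rep), 1)
  expect_match(rep$message, "reference")

  s <- toy_strata()
  s$emp_ft[2] <- 0.80
  s$emp_pt[2] <- 0.25  # sums to 1.05
  rep <- validate_strata(s)
  expect_equal(nrow(rep), 1)
  expect_match(rep$where, "female 50-54")

  # idempotent and side-effect free
  expect_identical(validate_strata(s), validate_strata(s))
})

test_that("config files round-trip with defaults for omitted keys", {
  path <- withr::local_tempfile(fileext = ".ini")
  writeLines(c("[fiscal]", "vat_rate = 0.10", "tax_wedge = 0.327",
               "[modifiers]", "beta_employment = -0.04",
               "[run]", "age_hi = 65"), path)
  cfg <- load_config(path)
  expect_equal(cfg$fiscal$vat_rate, 0.10)
  expect_equal(cfg$fiscal$tax_wedge, 0.327)
  expect_equal(cfg$fiscal$sickpay_fraction, 2 / 3)  # documented default
  expect_equal(cfg$modifiers$beta_employment, -0.04)
  expect_equal(cfg$run$age_hi, 65)
  expect_identical(cfg$run$oao_set, c("overweight", "obese"))
})

test_that("config validation and unknown-key handling", {
  path <- withr::local_tempfile(fileext = ".ini")
  writeLines(c("[fiscal]", "vat_rate = 1.5"), path)
  expect_error(load_config(path), "vat_rate")

  writeLines(c("[fiscal]", "vat_rate = 0.1", "frobnicate = 3"), path)
  expect_warning(cfg <- load_config(path), "frobnicate")
  expect_equal(cfg$fiscal$vat_rate, 0.1)
})

test_that("full config round-trip preserves parameters incl. sex splits", {
  fis <- fiscal_params(tax_wedge = 0.3, pension_benefit = 1.5e6)
  mod <- modifier_set(beta_employment = c(male = -0.02, female = -0.06),
                      beta_income = -0.05, hr_sickleave = 1.3,
                      rr_mortality = c(underweight = 1.1, normal = 1,
                                       overweight = 1.2, obese = 1.4),
                      rr_mortality_elderly = c(underweight = 1.3, normal = 1,
                                               overweight = 1.05,
                                               obese = 1.2),
                      af_healthcare = 0.05)
  path <- withr::local_tempfile(fileext = ".ini")
  write_config(fis, mod, path, run = list(oao_set = "obese"))
  cfg <- load_config(path)
  expect_equal(cfg$fiscal$tax_wedge, 0.3)
  expect_equal(cfg$fiscal$pension_benefit, 1.5e6)
  expect_equal(cfg$modifiers$beta_employment,
               c(male = -0.02, female = -0.06))
  expect_equal(cfg$modifiers$rr_mortality[["obese"]], 1.4)
  expect_equal(cfg$modifiers$rr_mortality_elderly[["underweight"]], 1.3)
  expect_identical(cfg$run$oao_set, "obese")
})

test_that("life tables round-trip and are validated", {
  inp <- japan_like_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_life_table(inp$life_table, path)
  lt <- read_life_table(path)
  expect_equal(lt$qx, inp$life_table$qx, tolerance = 1e-9)

  bad <- inp$life_table
  bad$qx[bad$age == 105] <- 0.5
  write_life_table(bad, path)
  expect_error(read_life_table(path), "terminal")
})

test_that("constructors reject out-of-range parameters", {
  expect_error(fiscal_params(vat_rate = 1.5), "vat_rate")
  expect_error(modifier_set(af_healthcare = 1), "af_healthcare")
  expect_error(modifier_set(hr_sickleave = -1), "hazard")
  expect_error(modifier_set(rr_mortality = c(underweight = 1, normal = 1.2,
                                             overweight = 1, obese = 1)),
               "reference")
})
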