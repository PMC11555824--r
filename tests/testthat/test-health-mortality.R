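# Attributable-fraction redistribution of healthcare costs and
# Rockhill-PAF mortality.

test_that("MEPC redistribution matches the worked example and conserves
           the mean", {
  prev <- c(underweight = 0.1, normal = 0.65, overweight = 0.15, obese = 0.10)
  out <- adjust_mepc(100, prev, 0.1)
  expect_equal(unname(out["normal"]), 90)
  expect_equal(unname(out["overweight"]), 90 + 10 / 0.25)
  expect_equal(unname(out["obese"]), 130)
  expect_equal(sum(prev * out), 100, tolerance = 1e-12)  # conservation

  # af = 0: everyone keeps the population mean
  expect_equal(unname(adjust_mepc(100, prev, 0)), rep(100, 4))

  # single exposed group gets exactly the mean back
  prev1 <- c(underweight = 0, normal = 0, overweight = 0.6, obese = 0.4)
  out1 <- adjust_mepc(100, prev1, 0.1)
  expect_equal(sum(prev1 * out1), 100, tolerance = 1e-12)
  expect_equal(unname(out1["overweight"]), 90 + 10)

  expect_error(adjust_mepc(100, c(underweight = 0.3, normal = 0.7,
                                  overweight = 0, obese = 0), 0.1),
               "exposed")
})

test_that("MEPC conservation holds across random prevalences and fractions", {
  set.seed(42)
  for (i in 1:50) {
    p <- stats::rgamma(4, 1) + 0.01
    p <- stats::setNames(p / sum(p),
                         c("underweight", "normal", "overweight", "obese"))
    af <- stats::runif(1, 0, 0.95)
    m <- stats::runif(1, 1e4, 1e6)
    expect_equal(sum(p * adjust_mepc(m, p, af)), m, tolerance = 1e-9)
  }
})

test_that("Rockhill PAF matches hand evaluation and closed forms", {
  pd <- c(underweight = 0.3, normal = 0.4, overweight = 0.2, obese = 0.1)
  rr <- c(underweight = 1, normal = 1, overweight = 1.25, obese = 1.5)
  expect_equal(rockhill_paf(pd, rr), 0.2 * 0.2 + 0.1 * (1 / 3),
               tolerance = 1e-12)
  # null association
  expect_equal(rockhill_paf(pd, c(underweight = 1, normal = 1,
                                  overweight = 1, obese = 1)), 0)
  # single category closed form (rr - 1) / rr
  expect_equal(rockhill_paf(c(obese = 1), c(obese = 2, normal = 1)), 0.5)
  # uniform pd with identical rr r collapses to (r - 1) / r
  r <- 1.7
  pdu <- c(underweight = 0.25, normal = 0.25, overweight = 0.25, obese = 0.25)
  expect_equal(rockhill_paf(pdu, c(underweight = r, normal = r,
                                   overweight = r, obese = r)),
               (r - 1) / r, tolerance = 1e-12)
  expect_error(rockhill_paf(c(obese = 1), c(obese = 0, normal = 1)), "rr")
})

test_that("Rockhill PAF is monotone in rr and in pd of risky categories", {
  pd <- c(underweight = 0.1, normal = 0.6, overweight = 0.2, obese = 0.1)
  rr <- c(underweight = 1, normal = 1, overweight = 1.2, obese = 1.5)
  base <- rockhill_paf(pd, rr)
  for (d in c(0.1, 0.5, 1)) {
    rr2 <- rr; rr2[["obese"]] <- rr[["obese"]] + d
    expect_gt(rockhill_paf(pd, rr2), base)
  }
  pd2 <- pd
  pd2[["obese"]] <- pd[["obese"]] + 0.1
  pd2[["normal"]] <- pd[["normal"]] - 0.1
  expect_gt(rockhill_paf(pd2, rr), base)
})

test_that("death distribution is the rr-weighted prevalence", {
  prev <- c(underweight = 0.1, normal = 0.7, overweight = 0.15, obese = 0.05)
  rr <- c(underweight = 1, normal = 1, overweight = 1.25, obese = 1.5)
  pd <- death_distribution(prev, rr)
  expect_equal(sum(pd), 1, tolerance = 1e-12)
  expect_equal(unname(pd["obese"]),
               0.05 * 1.5 / sum(prev * rr), tolerance = 1e-12)
})

test_that("excess deaths combine PAF, counts and band-averaged qx", {
  lt <- data.frame(sex = "male", age = 40:49, qx = rep(0.01, 10))
  strata <- toy_strata()[1, ]
  out <- excess_deaths(0.07333, lt, strata)
  expect_equal(out$deaths_total, 1000 * 0.01)
  expect_equal(out$oao_deaths, 0.7333, tolerance = 1e-9)
  # zero PAF, zero OAO deaths
  expect_equal(excess_deaths(0, lt, strata)$oao_deaths, 0)
  # linear in population
  strata2 <- strata; strata2$count <- 2000
  expect_equal(excess_deaths(0.0733, lt, strata2)$oao_deaths,
               2 * excess_deaths(0.0733, lt, strata)$oao_deaths)
  # band not covered by the life table
  strata3 <- strata; strata3$age_hi <- 60
  expect_error(excess_deaths(0.1, lt, strata3), "40-60")
})

test_that("band_qx averages single-year qx over the band", {
  lt <- data.frame(sex = "female", age = 50:54, qx = c(1:5) / 100)
  expect_equal(band_qx(lt, "female", 50, 54), 0.03)
  expect_equal(band_qx(lt, "female", 51, 53), 0.03)
  expect_error(band_qx(lt, "female", 49, 54), "cover")
})
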