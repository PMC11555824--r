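# Per-person lifetime cohort model: an individual with OAO vs a
# non-OAO peer, fixed status for life, discounted to present value.

# carry the last band's rates forward beyond the oldest stratum band;
# employment is extinguished by retirement from the statutory age anyway
.age_row <- function(strata, sex, age) {
  b <- strata[strata$sex == sex, ]
  b <- b[order(b$age_lo), ]
  hit <- which(b$age_lo <= age & b$age_hi >= age)
  if (length(hit)) b[hit[1], ] else b[nrow(b), ]
}

#' Per-person lifetime fiscal effect of OAO
#'
#' Two arms are followed from `start_age` to the life table's terminal
#' age: a non-OAO individual and an OAO peer whose employment, income,
#' sick-leave and retirement rates carry the OAO modifiers and whose
#' annual death probability is scaled by the prevalence-weighted OAO
#' mortality relative risk. Neither arm can switch status. Both arms
#' face the same baseline early-retirement hazard from
#' `early_retirement_from` (the OAO arm's hazard is multiplied by the
#' retirement hazard ratio) and full statutory retirement at
#' `retirement_age`. The OAO arm's per-capita healthcare carries the
#' attributable-fraction mark-up at the age-specific OAO prevalence; the
#' peer carries the marked-down non-OAO expenditure.
#'
#' The life table's `qx` is treated as the population average and split
#' into arm-specific hazards
#' `qx_non = qx / (1 - p + p * rr)` and `qx_oao = rr * qx_non`,
#' where `p` is the age-specific OAO prevalence, so the population mix
#' reproduces the life table.
#'
#' Annual net flows (direct + indirect tax - pension - healthcare) are
#' weighted by start-of-year survival, wages and healthcare grow with
#' `wage_growth`, and flows are discounted at `discount_rate`. The
#' burden is `pv(non-OAO) - pv(OAO)` per person.
#'
#' @param start_age Age at entry (years); must lie within the life table.
#' @param modifiers,fiscal,life_table,strata Model inputs.
#' @param sex_mix Named weights over `male` / `female` (normalised).
#' @param oao_set Categories forming the OAO group.
#' @param retirement_age Statutory retirement age (pension from here).
#' @param early_retirement_from Age from which the baseline retirement
#'   hazard (stratum `retirement` rate) operates in both arms.
#' @param use_elderly_rr Use the alternate relative risks at >= 65.
#' @return An object of class `fbod_lifetime`: `$total` (per-person
#'   lifetime burden, JPY), `$tax_loss`, `$transfer_excess`
#'   (`total = tax_loss + transfer_excess`), `$pv` (per-arm present
#'   values), and `$detail` (per-age, per-arm flow table).
#' @export
lifetime_fiscal_effect <- function(start_age, modifiers, fiscal, life_table,
                                   strata,
                                   sex_mix = c(male = 0.5, female = 0.5),
                                   oao_set = c("overweight", "obese"),
                                   retirement_age = 65,
                                   early_retirement_from = 50,
                                   use_elderly_rr = FALSE) {
  sex_mix <- sex_mix / sum(sex_mix)
  sex_mix <- sex_mix[sex_mix > 0]
  per_sex <- lapply(names(sex_mix), function(sx) {
    .lifetime_one_sex(start_age, sx, modifiers, fiscal, life_table, strata,
                      oao_set, retirement_age, early_retirement_from,
                      use_elderly_rr)
  })
  w <- unname(sex_mix)
  tax_loss <- sum(w * vapply(per_sex, `[[`, numeric(1), "tax_loss"))
  transfer_excess <- sum(w * vapply(per_sex, `[[`, numeric(1),
                                    "transfer_excess"))
  pv <- c(non_oao = sum(w * vapply(per_sex, function(x) x$pv[["non_oao"]],
                                   numeric(1))),
          oao = sum(w * vapply(per_sex, function(x) x$pv[["oao"]],
                               numeric(1))))
  structure(list(start_age = start_age, sex_mix = sex_mix,
                 total = tax_loss + transfer_excess,
                 tax_loss = tax_loss, transfer_excess = transfer_excess,
                 pv = pv,
                 detail = do.call(rbind, lapply(per_sex, `[[`, "detail"))),
            class = "fbod_lifetime")
}

.lifetime_one_sex <- function(start_age, sex, modifiers, fiscal, life_table,
                              strata, oao_set, retirement_age,
                              early_retirement_from, use_elderly_rr) {
  lt <- life_table[life_table$sex == sex, ]
  if (!nrow(lt)) stop("life table has no rows for sex ", sex)
  lt <- lt[order(lt$age), ]
  terminal <- max(lt$age)
  if (start_age > terminal || start_age < min(lt$age))
    stop("start_age outside the life table range")
  ages <- start_age:terminal
  d <- fiscal$discount_rate
  wg <- fiscal$wage_growth
  b_e <- .mod_value(modifiers$beta_employment, sex)
  b_y <- .mod_value(modifiers$beta_income, sex)
  hr_sl <- .mod_value(modifiers$hr_sickleave, sex)
  hr_rt <- .mod_value(modifiers$hr_retirement, sex)
  af <- modifiers$af_healthcare

  s_non <- s_oao <- 1       # start-of-year survival
  ret_non <- ret_oao <- 0   # retired-state probability
  pv_non <- pv_oao <- 0
  pv_tax_non <- pv_tax_oao <- 0
  pv_spend_non <- pv_spend_oao <- 0
  detail <- vector("list", length(ages))

  for (i in seq_along(ages)) {
    a <- ages[i]
    t <- a - start_age
    row <- .age_row(strata, sex, a)
    rr_map <- modifiers$rr_mortality
    if (use_elderly_rr && !is.null(modifiers$rr_mortality_elderly) && a >= 65)
      rr_map <- modifiers$rr_mortality_elderly
    props <- stats::setNames(c(row$p_under, row$p_normal, row$p_over,
                               row$p_obese), .bmi_labels)
    p_oao <- sum(props[oao_set])
    rr_w <- .oao_weighted_rr(props, rr_map, oao_set)

    qx <- lt$qx[lt$age == a]
    qx_non <- min(1, qx / (1 - p_oao + p_oao * rr_w))
    qx_oao <- min(1, rr_w * qx_non)
    if (a == terminal) qx_non <- qx_oao <- 1

    # retirement-state update (both arms share the baseline hazard; the
    # OAO arm's is scaled by the hazard ratio)
    if (a >= retirement_age) {
      ret_non <- ret_oao <- 1
    } else if (a >= early_retirement_from) {
      h <- .clamp01(row$retirement)
      ret_non <- ret_non + (1 - ret_non) * h
      ret_oao <- ret_oao + (1 - ret_oao) * .clamp01(h * hr_rt)
    }

    growth <- (1 + wg)^t
    disc <- (1 + d)^(-t)

    arm_flows <- function(arm) {
      oao <- arm == "oao"
      grp <- if (oao) "OAO" else "reference"
      ret <- if (oao) ret_oao else ret_non
      p_ft <- adjust_employment(row$emp_ft, if (oao) b_e else 0, grp) *
        (1 - ret)
      p_pt <- adjust_employment(row$emp_pt, if (oao) b_e else 0, grp) *
        (1 - ret)
      p_sl <- adjust_welfare_rate(row$sickleave, if (oao) hr_sl else 1)
      y_ft <- adjust_income(row$income_ft, if (oao) b_y else 0, grp) * growth
      y_pt <- adjust_income(row$income_pt, if (oao) b_y else 0, grp) * growth
      lab <- total_income(1, p_ft, p_pt, p_sl, ret, y_ft, y_pt, fiscal)
      dt <- direct_tax(lab$income_total, fiscal)
      it <- indirect_tax(lab$disposable_income, lab$transfer_income, fiscal)
      hc <- if (oao) {
        mepc <- if (af > 0 && p_oao > 0)
          (1 - af) * row$mepc + af * row$mepc / p_oao
        else row$mepc
        mepc * growth
      } else {
        (if (af > 0 && p_oao > 0) (1 - af) * row$mepc else row$mepc) * growth
      }
      c(tax = dt + it, spend = lab$transfer_income + hc)
    }
    fn <- arm_flows("non_oao")
    fo <- arm_flows("oao")
    pv_tax_non <- pv_tax_non + disc * s_non * fn[["tax"]]
    pv_tax_oao <- pv_tax_oao + disc * s_oao * fo[["tax"]]
    pv_spend_non <- pv_spend_non + disc * s_non * fn[["spend"]]
    pv_spend_oao <- pv_spend_oao + disc * s_oao * fo[["spend"]]
    pv_non <- pv_non + disc * s_non * (fn[["tax"]] - fn[["spend"]])
    pv_oao <- pv_oao + disc * s_oao * (fo[["tax"]] - fo[["spend"]])
    detail[[i]] <- data.frame(sex = sex, age = a,
                              surv_non = s_non, surv_oao = s_oao,
                              tax_non = fn[["tax"]], tax_oao = fo[["tax"]],
                              spend_non = fn[["spend"]],
                              spend_oao = fo[["spend"]])
    s_non <- s_non * (1 - qx_non)
    s_oao <- s_oao * (1 - qx_oao)
  }
  list(tax_loss = pv_tax_non - pv_tax_oao,
       transfer_excess = pv_spend_oao - pv_spend_non,
       pv = c(non_oao = pv_non, oao = pv_oao),
       detail = do.call(rbind, detail))
}

#' Lifetime burden across starting ages (and sex splits)
#'
#' Applies [lifetime_fiscal_effect()] at each starting age; `sex` selects
#' a male-only, female-only or mixed cohort.
#'
#' @param ages Vector of starting ages.
#' @param sex `"both"`, `"male"` or `"female"`.
#' @param ... Passed to [lifetime_fiscal_effect()] (must include
#'   `modifiers`, `fiscal`, `life_table`, `strata`).
#' @return A data frame with columns `age`, `tax_loss`,
#'   `transfer_excess`, `total` (JPY per person).
#' @export
lifetime_age_sweep <- function(ages, sex = c("both", "male", "female"), ...) {
  sex <- match.arg(sex)
  mix <- switch(sex, both = c(male = 0.5, female = 0.5),
                male = c(male = 1, female = 0),
                female = c(male = 0, female = 1))
  rows <- lapply(ages, function(a) {
    r <- lifetime_fiscal_effect(a, sex_mix = mix, ...)
    data.frame(age = a, tax_loss = r$tax_loss,
               transfer_excess = r$transfer_excess, total = r$total)
  })
  do.call(rbind, rows)
}
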