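# Shared toy fixtures and an independent spreadsheet-style ledger.
#
# The ledger re-derives every fiscal flow with explicit scalar
# arithmetic, straight from the model equations (employment shifted
# additively, welfare rates scaled by hazard ratios, income shifted
# relatively, tax wedge on total income, VAT on disposable plus transfer
# income, attributable-fraction redistribution of per-capita healthcare,
# Rockhill death share with a half-year person-time loss per death). It
# never calls the engine, so it can serve as its oracle.

toy_strata <- function() {
  data.frame(
    age_lo = c(40, 50), age_hi = c(44, 54),
    sex = c("male", "female"), count = c(1000, 800),
    p_under = c(0.10, 0.12), p_normal = c(0.70, 0.68),
    p_over = c(0.15, 0.14), p_obese = c(0.05, 0.06),
    emp_ft = c(0.80, 0.60), emp_pt = c(0.10, 0.25),
    income_ft = c(4e6, 3e6), income_pt = c(1.2e6, 1.0e6),
    sickleave = c(0.05, 0.04), retirement = c(0.02, 0.05),
    mepc = c(2e5, 3e5), mortality = c(0.002, 0.004),
    stringsAsFactors = FALSE)
}

toy_modifiers <- function() {
  modifier_set(beta_employment = -0.05, beta_income = -0.03,
               hr_sickleave = 1.4, hr_retirement = 1.2,
               rr_mortality = c(underweight = 1, normal = 1,
                                overweight = 1.25, obese = 1.5),
               af_healthcare = 0.1)
}

toy_fiscal <- function() {
  fiscal_params(tax_wedge = 0.327, vat_rate = 0.10, pension_benefit = 2e6,
                sickpay_fraction = 2 / 3)
}

# ---- hand ledger -----------------------------------------------------------

# flows of one (stratum, category) cell; every quantity spelled out
ledger_cell <- function(n, prop, oao, s, mod, fis, ref_props, oao_set,
                        deaths_in_cat, mortality_adjust = TRUE) {
  n_k <- n * prop
  if (n_k <= 0) {
    return(c(direct = 0, indirect = 0, transfers = 0, healthcare = 0))
  }
  b_e <- if (oao) mod$beta_employment else 0
  b_y <- if (oao) mod$beta_income else 0
  hr_sl <- if (oao) mod$hr_sickleave else 1
  hr_rt <- if (oao) mod$hr_retirement else 1
  p_ret <- min(1, max(0, s$retirement * hr_rt))
  p_ft <- min(1, max(0, s$emp_ft + b_e)) * (1 - p_ret)
  p_pt <- min(1, max(0, s$emp_pt + b_e)) * (1 - p_ret)
  p_sl <- min(1, max(0, s$sickleave * hr_sl))
  y_ft <- max(0, s$income_ft * (1 + b_y))
  y_pt <- max(0, s$income_pt * (1 + b_y))
  income <- n_k * (p_ft * (1 - p_sl) * y_ft +
                     p_pt * y_pt +
                     p_ft * p_sl * fis$sickpay_fraction * y_ft)
  transfer <- n_k * p_ret * fis$pension_benefit
  if (mortality_adjust && oao) {
    surv <- max(0, 1 - 0.5 * deaths_in_cat / n_k)
    income <- income * surv
    transfer <- transfer * surv
  }
  direct <- fis$tax_wedge * income
  indirect <- fis$vat_rate * (income * (1 - fis$tax_wedge) + transfer)
  af <- mod$af_healthcare
  p_ref <- sum(ref_props[oao_set])
  mepc <- if (af > 0 && p_ref > 0) {
    if (oao) (1 - af) * s$mepc + af * s$mepc / p_ref else (1 - af) * s$mepc
  } else s$mepc
  c(direct = direct, indirect = indirect, transfers = transfer,
    healthcare = n_k * mepc)
}

# full-population ledger: control or intervention flows
ledger_flows <- function(strata, mod, fis, role = "control",
                         oao_set = c("overweight", "obese"),
                         mortality_adjust = TRUE) {
  labels <- c("underweight", "normal", "overweight", "obese")
  tot <- c(direct = 0, indirect = 0, transfers = 0, healthcare = 0)
  for (i in seq_len(nrow(strata))) {
    s <- strata[i, ]
    ref <- c(underweight = s$p_under, normal = s$p_normal,
             overweight = s$p_over, obese = s$p_obese)
    props <- ref
    if (role == "intervention") {
      props["normal"] <- props["normal"] + sum(props[oao_set])
      props[oao_set] <- 0
    }
    rr <- mod$rr_mortality
    # Rockhill share of deaths in the OAO categories, from the cohort's
    # own prevalence
    w <- props * rr[labels]
    deaths_k <- setNames(rep(0, 4), labels)
    if (sum(props[oao_set]) > 0) {
      pd <- w / sum(w)
      paf <- sum(pd[oao_set] * (rr[oao_set] - 1) / rr[oao_set])
      oao_deaths <- paf * s$count * s$mortality
      deaths_k[oao_set] <- oao_deaths * w[oao_set] / sum(w[oao_set])
    }
    for (k in labels) {
      tot <- tot + ledger_cell(s$count, props[[k]], k %in% oao_set, s, mod,
                               fis, ref, oao_set, deaths_k[[k]],
                               mortality_adjust)
    }
  }
  tot
}

# three-age lifetime ledger (start 63, terminal 65), one sex
ledger_lifetime <- function(s, mod, fis, qx_vec, p_oao, retirement_age = 65) {
  rr_w <- (s$p_over * mod$rr_mortality[["overweight"]] +
             s$p_obese * mod$rr_mortality[["obese"]]) / (s$p_over + s$p_obese)
  arms <- list()
  for (arm in c("non", "oao")) {
    oao <- arm == "oao"
    b_e <- if (oao) mod$beta_employment else 0
    b_y <- if (oao) mod$beta_income else 0
    hr_sl <- if (oao) mod$hr_sickleave else 1
    hr_rt <- if (oao) mod$hr_retirement else 1
    surv <- 1; ret <- 0
    pv_tax <- 0; pv_spend <- 0
    for (i in seq_along(qx_vec)) {
      a <- 63 + i - 1
      t <- a - 63
      if (a >= retirement_age) ret <- 1
      else ret <- ret + (1 - ret) * min(1, s$retirement * hr_rt)
      growth <- (1 + fis$wage_growth)^t
      disc <- (1 + fis$discount_rate)^(-t)
      p_ft <- min(1, max(0, s$emp_ft + b_e)) * (1 - ret)
      p_pt <- min(1, max(0, s$emp_pt + b_e)) * (1 - ret)
      p_sl <- min(1, s$sickleave * hr_sl)
      y_ft <- max(0, s$income_ft * (1 + b_y)) * growth
      y_pt <- max(0, s$income_pt * (1 + b_y)) * growth
      income <- p_ft * (1 - p_sl) * y_ft + p_pt * y_pt +
        p_ft * p_sl * fis$sickpay_fraction * y_ft
      pension <- ret * fis$pension_benefit
      tax <- fis$tax_wedge * income +
        fis$vat_rate * (income * (1 - fis$tax_wedge) + pension)
      af <- mod$af_healthcare
      hc <- if (af > 0 && p_oao > 0) {
        if (oao) (1 - af) * s$mepc + af * s$mepc / p_oao
        else (1 - af) * s$mepc
      } else s$mepc
      hc <- hc * growth
      pv_tax <- pv_tax + disc * surv * tax
      pv_spend <- pv_spend + disc * surv * (pension + hc)
      qx_non <- min(1, qx_vec[i] / (1 - p_oao + p_oao * rr_w))
      qx_arm <- if (oao) min(1, rr_w * qx_non) else qx_non
      if (i == length(qx_vec)) qx_arm <- 1
      surv <- surv * (1 - qx_arm)
    }
    arms[[arm]] <- c(tax = pv_tax, spend = pv_spend)
  }
  list(tax_loss = arms$non[["tax"]] - arms$oao[["tax"]],
       transfer_excess = arms$oao[["spend"]] - arms$non[["spend"]],
       total = (arms$non[["tax"]] - arms$non[["spend"]]) -
         (arms$oao[["tax"]] - arms$oao[["spend"]]))
}
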