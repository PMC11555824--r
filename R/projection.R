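# Multi-year projection of the fiscal burden under prevalence growth,
# wage growth and discounting.

#' Project the fiscal burden over a multi-year horizon
#'
#' For each year `t = 0, ..., horizon`, the combined OAO prevalence of
#' each stratum is grown multiplicatively at the sex-specific annual rate
#' (the mass is drawn from the normal-weight category, preserving the
#' internal overweight:obese ratio, and clamped so normal weight stays
#' non-negative), wages are scaled by `(1 + wage_growth)^t`, the burden
#' is recomputed, and the total is discounted at
#' `(1 + discount_rate)^-t`. The base year (`t = 0`) is undiscounted.
#'
#' Population counts are held constant over the horizon unless a
#' projection table (`year, sex, age_lo, age_hi, count`) is supplied.
#' Per-capita medical expenditure grows with wages by default
#' (`grow_mepc = TRUE`); pension benefits are held fixed in real terms.
#'
#' @param fit An `fbod` object (base-year fit), or a stratum data frame
#'   with `modifiers` and `fiscal` supplied.
#' @param horizon Years beyond the base year (default
#'   `fiscal$horizon_years`).
#' @param base_year Calendar label of year 0 (reporting only).
#' @param population Optional projected counts data frame.
#' @param grow_mepc Grow per-capita medical expenditure with wages.
#' @param modifiers,fiscal,... Used when `fit` is a stratum table.
#' @return An object of class `fbod_projection`: `$per_year` (one row per
#'   year with burden components, total and discounted total),
#'   `$npv_total` (sum of discounted totals) and `$base_year`.
#' @export
project_burden <- function(fit, horizon = NULL, base_year = 2023,
                           population = NULL, grow_mepc = TRUE,
                           modifiers = NULL, fiscal = NULL, ...) {
  if (!inherits(fit, "fbod"))
    fit <- fiscal_bod(fit, modifiers, fiscal, ...)
  fiscal <- fit$fiscal
  if (is.null(horizon)) horizon <- fiscal$horizon_years
  if (horizon < 1) stop("horizon must be >= 1")
  if (is.null(population))
    message("no population projection supplied; counts held constant")
  o <- fit$options
  base <- fit$control$strata
  rows <- vector("list", horizon + 1)
  for (t in 0:horizon) {
    st <- .grow_strata(base, fiscal, t, o$oao_set, grow_mepc, population,
                       base_year)
    b <- fiscal_bod(st, fit$modifiers, fiscal, oao_set = o$oao_set,
                    age_range = NULL, sex = "both",
                    sickleave_scope = o$sickleave_scope,
                    use_elderly_rr = o$use_elderly_rr,
                    mortality_adjust = o$mortality_adjust)
    comp <- coef(b)
    disc <- (1 + fiscal$discount_rate)^(-t)
    rows[[t + 1]] <- data.frame(
      year = base_year + t, t = t,
      direct_tax_loss = comp[["direct_tax_loss"]],
      indirect_tax_loss = comp[["indirect_tax_loss"]],
      transfer_excess = comp[["transfer_excess"]],
      healthcare_excess = comp[["healthcare_excess"]],
      total = b$burden$total,
      discounted_total = b$burden$total * disc)
  }
  per_year <- do.call(rbind, rows)
  structure(list(per_year = per_year,
                 npv_total = sum(per_year$discounted_total),
                 base_year = base_year, horizon = horizon,
                 fiscal = fiscal),
            class = "fbod_projection")
}

# year-t stratum table: grown OAO prevalence, grown wages (and MEPC)
.grow_strata <- function(strata, fiscal, t, oao_set, grow_mepc,
                         population, base_year) {
  st <- strata
  # sex filtering in fiscal_bod zeroes counts but the sexes keep their
  # own growth rates
  for (i in seq_len(nrow(st))) {
    g <- fiscal$prevalence_growth[[st$sex[i]]]
    p0 <- sum(vapply(oao_set, function(k) st[i, .bmi_cols[[k]]], numeric(1)))
    if (p0 <= 0) next
    p_t <- p0 * (1 + g)^t
    cap <- p0 + st$p_normal[i]
    if (p_t > cap) {
      warning(sprintf(
        "OAO prevalence clamped at %.3f for stratum %s %d-%d (year %d)",
        cap, st$sex[i], st$age_lo[i], st$age_hi[i], t))
      p_t <- cap
    }
    scale <- p_t / p0
    for (k in oao_set) {
      col <- .bmi_cols[[k]]
      st[i, col] <- st[i, col] * scale
    }
    # snap tiny negatives from the clamp arithmetic back to the simplex
    st$p_normal[i] <- max(0, st$p_normal[i] - (p_t - p0))
  }
  wf <- (1 + fiscal$wage_growth)^t
  st$income_ft <- st$income_ft * wf
  st$income_pt <- st$income_pt * wf
  if (grow_mepc) st$mepc <- st$mepc * wf
  # the per-category MEPC profile stays anchored to the base-year control
  # prevalence, so the per-OAO-person healthcare mark-up is the structural
  # constant and excess healthcare spending grows with OAO prevalence
  if (!is.null(population)) {
    yr <- base_year + t
    p <- population[population$year == yr, ]
    if (nrow(p)) {
      key_s <- paste(st$sex, st$age_lo, st$age_hi)
      key_p <- paste(p$sex, p$age_lo, p$age_hi)
      hit <- match(key_s, key_p)
      st$count[!is.na(hit)] <- p$count[hit[!is.na(hit)]]
    }
  }
  st
}

#' Growth of the fiscal burden over a projection
#'
#' The percentage change between the first and last discounted annual
#' totals of a projection (with wage growth equal to the discount rate,
#' this isolates the prevalence-growth effect).
#'
#' @param proj An `fbod_projection`.
#' @return Percentage change (e.g. `15` for a 15% increase).
#' @export
decade_growth <- function(proj) {
  py <- proj$per_year
  100 * (py$discounted_total[nrow(py)] / py$discounted_total[1] - 1)
}
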