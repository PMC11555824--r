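# Healthcare-cost redistribution and OAO-attributable mortality.

#' Redistribute per-capita medical expenditure by attributable fraction
#'
#' A fraction `af` of total medical spending is attributable to OAO. The
#' general-population mean expenditure `mepc_gp` is adjusted downward for
#' the non-OAO categories, which receive `(1 - af) * mepc_gp`, and upward
#' for the OAO categories, which additionally receive the attributable
#' spend spread over the OAO prevalence `p`:
#' `(1 - af) * mepc_gp + af * mepc_gp / p`. The prevalence-weighted mean
#' of the adjusted values equals `mepc_gp` exactly (conservation).
#'
#' @param mepc_gp Mean medical expenditure per capita (currency/year).
#' @param prevalence Named simplex over the four BMI categories.
#' @param af Attributable fraction in `[0, 1)`.
#' @param oao_set Labels of the categories forming the OAO group.
#' @return Named vector of adjusted per-capita expenditure by category.
#' @examples
#' adjust_mepc(100, c(underweight = 0.1, normal = 0.65,
#'                    overweight = 0.15, obese = 0.10), 0.1)
#' @export
adjust_mepc <- function(mepc_gp, prevalence, af,
                        oao_set = c("overweight", "obese")) {
  .check_oao_set(oao_set)
  if (af < 0 || af >= 1) stop("af must be in [0,1)")
  p <- sum(prevalence[oao_set])
  if (af > 0 && p <= 0)
    stop("attributable fraction > 0 with no exposed (OAO) population")
  out <- stats::setNames(rep((1 - af) * mepc_gp, length(prevalence)),
                         names(prevalence))
  if (af > 0) out[oao_set] <- out[oao_set] + af * mepc_gp / p
  out
}

#' Population attributable fraction (Rockhill formula)
#'
#' `PAF = sum_k pd_k * (rr_k - 1) / rr_k`, where `pd_k` is the proportion
#' of cases (here, deaths) in BMI category `k` and `rr_k` the relative
#' risk with normal weight as reference. Equals 0 when all relative risks
#' are 1; is bounded above by 1.
#'
#' @param pd Named simplex: proportion of deaths per category.
#' @param rr Named relative risks; `rr["normal"]` must be 1.
#' @param categories Categories to include in the sum (default all;
#'   restrict to the OAO categories to obtain the OAO-specific fraction).
#' @return The attributable fraction.
#' @examples
#' rockhill_paf(pd = c(underweight = 0.3, normal = 0.4,
#'                     overweight = 0.2, obese = 0.1),
#'              rr = c(underweight = 1, normal = 1,
#'                     overweight = 1.25, obese = 1.5))
#' @export
rockhill_paf <- function(pd, rr, categories = names(pd)) {
  if (abs(sum(pd) - 1) > 1e-9) stop("pd must sum to 1")
  if (any(rr < 0)) stop("relative risks must be >= 0")
  k <- intersect(categories, names(pd))
  if (any(rr[k] == 0 & pd[k] > 0))
    stop("rr = 0 with positive case proportion")
  terms <- pd[k] * (rr[k] - 1) / rr[k]
  terms[pd[k] == 0] <- 0
  sum(terms)
}

#' Derive the case (death) distribution from prevalence and relative risk
#'
#' When the proportion of deaths per BMI category is not observed
#' directly, it is constructed from prevalence and relative risk as
#' `pd_k = X_k rr_k / sum_j X_j rr_j`.
#'
#' @param prevalence Named simplex over categories.
#' @param rr Named relative risks.
#' @return Named simplex of death proportions.
#' @export
death_distribution <- function(prevalence, rr) {
  w <- prevalence * rr[names(prevalence)]
  if (sum(w) <= 0) stop("degenerate prevalence/rr combination")
  w / sum(w)
}

# prevalence-weighted RR of the OAO categories (used to scale qx in the
# lifetime model); returns 1 when the OAO prevalence is zero
.oao_weighted_rr <- function(prevalence, rr, oao_set) {
  p <- sum(prevalence[oao_set])
  if (p <= 0) return(1)
  sum(prevalence[oao_set] * rr[oao_set]) / p
}

# OAO-specific attributable fraction for a stratum: Rockhill terms of the
# OAO categories only, with pd derived from prevalence and rr
.stratum_oao_paf <- function(prevalence, rr, oao_set) {
  if (sum(prevalence[oao_set]) <= 0) return(0)
  pd <- death_distribution(prevalence, rr)
  rockhill_paf(pd, rr, categories = oao_set)
}

#' Band-averaged annual death probability from a life table
#'
#' @param life_table Data frame `sex, age, qx` (single-year ages).
#' @param sex Sex label.
#' @param age_lo,age_hi Closed age band.
#' @return Unweighted mean of `qx` over the band's single-year ages.
#' @export
band_qx <- function(life_table, sex, age_lo, age_hi) {
  q <- life_table[life_table$sex == sex &
                    life_table$age >= age_lo & life_table$age <= age_hi, ]
  if (nrow(q) != age_hi - age_lo + 1)
    stop(sprintf("life table does not cover band %d-%d (%s)",
                 age_lo, age_hi, sex))
  mean(q$qx)
}

#' Annual OAO-attributable deaths per stratum
#'
#' Deaths in each (age band, sex) stratum are the population count times
#' the band-averaged annual death probability from the life table; the
#' OAO-specific share is the population attributable fraction.
#'
#' @param paf Attributable fraction in `[0, 1)` (scalar, or a vector of
#'   per-stratum values recycled against the strata rows).
#' @param life_table Life-table data frame.
#' @param strata Stratum table.
#' @return `strata` with columns `deaths_total` and `oao_deaths` added.
#' @export
excess_deaths <- function(paf, life_table, strata) {
  if (any(paf < 0 | paf >= 1)) stop("paf must be in [0,1)")
  qx <- mapply(band_qx, sex = strata$sex, age_lo = strata$age_lo,
               age_hi = strata$age_hi, MoreArgs = list(life_table = life_table))
  out <- strata[, c("age_lo", "age_hi", "sex", "count")]
  out$deaths_total <- strata$count * qx
  out$oao_deaths <- paf * out$deaths_total
  out
}
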