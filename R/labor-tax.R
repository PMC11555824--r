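# Labor-market adjustment and tax-flow primitives.
#
# The OAO group's employment probability is shifted additively by the
# regression marginal effect; sick-leave and retirement rates are scaled
# by hazard ratios; income is shifted by a relative marginal effect.
# Direct tax is the tax wedge applied to total labor income; indirect tax
# is VAT on disposable income plus transfer income.

#' Adjust an employment probability for OAO status
#'
#' The marginal effect `beta` is additive on the probability scale (it is
#' the marginal effect from an employment regression). The reference
#' group is returned unchanged; the OAO group gets
#' `clamp(p + beta, 0, 1)`.
#'
#' @param p_gp Employment probability in the general population.
#' @param beta Additive marginal effect for the OAO group.
#' @param group `"reference"` or `"OAO"`.
#' @return Adjusted probability.
#' @examples
#' adjust_employment(0.80, -0.05, "OAO")  # 0.75
#' @export
adjust_employment <- function(p_gp, beta, group = c("reference", "OAO")) {
  group <- match.arg(group)
  if (any(p_gp < 0 | p_gp > 1)) stop("employment probability outside [0,1]")
  if (group == "reference") return(p_gp)
  .clamp01(p_gp + beta)
}

#' Adjust a social-welfare (sick-leave or retirement) rate for OAO status
#'
#' Population rates are multiplied by the published hazard ratio and
#' clamped to `[0, 1]`.
#'
#' @param rate_gp Annual rate in the general population, in `[0, 1]`.
#' @param hr Hazard ratio (>= 0); 1 leaves the rate unchanged.
#' @return Adjusted rate.
#' @export
adjust_welfare_rate <- function(rate_gp, hr) {
  if (any(rate_gp < 0 | rate_gp > 1)) stop("rate outside [0,1]")
  if (any(hr < 0)) stop("hazard ratio must be >= 0")
  .clamp01(rate_gp * hr)
}

#' Adjust labor income for OAO status
#'
#' The income marginal effect is relative: the OAO group earns
#' `y * (1 + beta_income)`, floored at zero.
#'
#' @param y_gp Annual income in the general population (currency).
#' @param beta_income Relative marginal effect (e.g. `-0.05`).
#' @param group `"reference"` or `"OAO"`.
#' @return Adjusted income.
#' @export
adjust_income <- function(y_gp, beta_income, group = c("reference", "OAO")) {
  group <- match.arg(group)
  if (any(y_gp < 0)) stop("income must be >= 0")
  if (group == "reference") return(y_gp)
  pmax(y_gp * (1 + beta_income), 0)
}

#' Aggregate labor income, disposable income and transfer income
#'
#' Total income for a group of `n` persons combines full-time workers not
#' on sick leave, part-time workers, and full-time workers on sick leave
#' receiving `sickpay_fraction` of their salary. Under
#' `sickleave_scope = "ft_and_pt"` the sick-leave split applies to both
#' employment types. Transfer income is pension payments to the retired.
#'
#' @param n Persons in the group.
#' @param p_ft,p_pt Employment probabilities (full-/part-time), already
#'   net of retirement.
#' @param p_sickleave Annual sick-leave probability.
#' @param p_retired Retired fraction.
#' @param y_ft,y_pt Annual full-/part-time income per worker.
#' @param fiscal An `fbod_fiscal` object (supplies `sickpay_fraction`,
#'   `tax_wedge` and `pension_benefit`).
#' @param sickleave_scope `"ft_only"` (base case) or `"ft_and_pt"`.
#' @return A list of class `fbod_labor` with `income_total`,
#'   `disposable_income` (`income_total * (1 - tax_wedge)`) and
#'   `transfer_income`, plus the rates used.
#' @export
total_income <- function(n, p_ft, p_pt, p_sickleave, p_retired, y_ft, y_pt,
                         fiscal, sickleave_scope = c("ft_only", "ft_and_pt")) {
  sickleave_scope <- match.arg(sickleave_scope)
  sp <- fiscal$sickpay_fraction
  ft_part <- p_ft * ((1 - p_sickleave) + p_sickleave * sp) * y_ft
  pt_part <- if (sickleave_scope == "ft_and_pt") {
    p_pt * ((1 - p_sickleave) + p_sickleave * sp) * y_pt
  } else {
    p_pt * y_pt
  }
  income_total <- n * (ft_part + pt_part)
  structure(list(p_ft = p_ft, p_pt = p_pt, p_sickleave = p_sickleave,
                 p_retired = p_retired,
                 income_total = income_total,
                 disposable_income = income_total * (1 - fiscal$tax_wedge),
                 transfer_income = n * p_retired * fiscal$pension_benefit),
            class = "fbod_labor")
}

#' Direct tax revenue via the tax wedge
#'
#' @param income_total Aggregate labor income (currency).
#' @param fiscal An `fbod_fiscal` object.
#' @return `tax_wedge * income_total`.
#' @export
direct_tax <- function(income_total, fiscal) {
  if (any(income_total < 0)) stop("income must be >= 0")
  fiscal$tax_wedge * income_total
}

#' Indirect (consumption) tax revenue
#'
#' VAT applied to disposable income (income after the tax wedge) and to
#' income from government transfers.
#'
#' @param disposable_income,transfer_income Currency amounts (>= 0).
#' @param fiscal An `fbod_fiscal` object.
#' @return `vat_rate * (disposable_income + transfer_income)`.
#' @export
indirect_tax <- function(disposable_income, transfer_income, fiscal) {
  if (any(disposable_income < 0) || any(transfer_income < 0))
    stop("tax base must be >= 0")
  fiscal$vat_rate * (disposable_income + transfer_income)
}
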